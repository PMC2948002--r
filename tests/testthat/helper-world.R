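# Shared builders for synthetic worlds used across the suites. All fixtures
# are built in code; nothing is read from disk except the tiny F_ST CSVs.

# A site table without going through a raster: deterministic covers.
make_sites <- function(region, n_forest, n_ecotone,
                       cover_forest = 85, cover_ecotone = 30,
                       spread = 8) {
  n <- n_forest + n_ecotone
  habitat <- rep(c("forest", "ecotone"), c(n_forest, n_ecotone))
  cover <- c(
    if (n_forest > 0)
      cover_forest + seq(-spread, spread, length.out = n_forest) else NULL,
    if (n_ecotone > 0)
      cover_ecotone + seq(-spread, spread, length.out = n_ecotone) else NULL)
  data.frame(
    site_id = sprintf("%s_s%02d", region, seq_len(n)),
    lon = seq_len(n), lat = seq_len(n), region = region, habitat = habitat,
    tree_cover = cover, potential_cover = cover,
    stringsAsFactors = FALSE)
}

# Individuals for one region in one call.
make_region_table <- function(region, n_forest_ind, n_ecotone_ind,
                              model = default_trait_model(),
                              n_forest_sites = 3, n_ecotone_sites = 3,
                              cover_forest = 85, cover_ecotone = 30,
                              seed = 1) {
  sites <- make_sites(region, n_forest_sites, n_ecotone_sites,
                      cover_forest, cover_ecotone)
  per_f <- diff(round(seq(0, n_forest_ind, length.out = n_forest_sites + 1)))
  per_e <- diff(round(seq(0, n_ecotone_ind,
                          length.out = n_ecotone_sites + 1)))
  counts <- stats::setNames(c(per_f, per_e), sites$site_id)
  generate_individuals(sites, model, counts, seed = seed)
}

# A flat-gradient "west": every site mid-cover, traits free of any cover
# effect (the homogenized world).
flat_model <- function() {
  default_trait_model(cover_slopes = c(tarsus = 0, wing = 0, tail = 0,
                                       upper_mandible = 0))
}

expect_abs_lt <- function(x, bound) expect_lt(abs(x), bound)
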