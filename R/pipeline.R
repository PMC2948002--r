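# Pipeline: one-config, end-to-end orchestration of the full analysis on
# synthetic or user-supplied inputs, with per-stage artifacts and a
# provenance log.

#' Build a validated run configuration
#'
#' All defaults are the analysis constants of the study design: 5 km
#' latitudinal bands, a 2.5 degree southward alignment shift for the
#' western region, a 10% deforestation threshold, 1000 bootstrap
#' replicates, family-wise alpha 0.05 over a family of 6 traits, and the
#' 1935 historical cutoff.
#'
#' @param west,central [region_spec()]s for the two regions (defaults: a
#'   flattened-gradient "west" and a steep-gradient "central" world).
#' @param model reference [trait_gen_model()] for central; `west_model`
#'   defaults to a divergence-free (zero-slope) variant of it.
#' @param west_model optional focal-region model.
#' @param n_sites named counts per region, e.g.
#'   `list(west = c(forest = 4, ecotone = 3), central = c(forest = 9, ecotone = 9))`.
#' @param n_per_site individuals per site (single count or named vector).
#' @param n_historical historical cohort size per region.
#' @param band_width_km,shift_deg,deforestation_threshold,B,alpha,m,
#'   historical_cutoff analysis constants (defaults above).
#' @param apply_shift_in_ancova shift the western band series before the
#'   ANCOVA (default TRUE).
#' @param seed global integer seed propagated to named substreams.
#' @return A `run_config` list.
#' @export
run_config <- function(west = NULL, central = NULL, model = NULL,
                       west_model = NULL,
                       n_sites = list(west = c(forest = 4, ecotone = 3),
                                      central = c(forest = 9, ecotone = 9)),
                       n_per_site = 6, n_historical = 25,
                       band_width_km = 5, shift_deg = 2.5,
                       deforestation_threshold = 10, B = 1000L,
                       alpha = 0.05, m = 6L, historical_cutoff = 1935,
                       apply_shift_in_ancova = TRUE, seed = 1L) {
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  if (band_width_km <= 0) stop("`band_width_km` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  central <- central %||% region_spec(
    "central", lat_range = c(2, 8), lon_range = c(10, 13),
    cover_intercept = 95, cover_slope = -12, noise_sd = 5,
    deforestation_fraction = 0.05, deforestation_depth = 30)
  west <- west %||% region_spec(
    "west", lat_range = c(5, 11), lon_range = c(-7, -4),
    cover_intercept = 70, cover_slope = -4, noise_sd = 5,
    deforestation_fraction = 0.35, deforestation_depth = 40)
  model <- model %||% default_trait_model()
  west_model <- west_model %||% default_trait_model(
    cover_slopes = c(tarsus = 0, wing = 0, tail = 0, upper_mandible = 0))
  structure(list(west = west, central = central, model = model,
                 west_model = west_model, n_sites = n_sites,
                 n_per_site = n_per_site, n_historical = n_historical,
                 band_width_km = band_width_km, shift_deg = shift_deg,
                 deforestation_threshold = deforestation_threshold,
                 B = as.integer(B), alpha = alpha, m = as.integer(m),
                 historical_cutoff = historical_cutoff,
                 apply_shift_in_ancova = apply_shift_in_ancova,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full gradient-flattening analysis end-to-end
#'
#' Executes, in order: synthetic-data generation (rasters, sites,
#' individuals, historical cohorts), gradient quantification (band means,
#' alignment, ANCOVA, deforestation mask), the trait-cover association
#' screen, morphometrics (covariance gate, pooled PCA, size correction),
#' habitat and era divergence testing, the stratified bootstrap null, and
#' trait projection. Per-stage artifacts (CSV, ASCII grids, a provenance
#' log) are written under `out_dir` when given.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A list of stage results (`rasters`, `band_series`, `ancova`,
#'   `deforestation`, `sites`, `individuals`, `historical`, `screen`,
#'   `divergence`, `era_divergence`, `bootstrap`, `projection`, `log`).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log <- character()

  # --- gradient substrate ---------------------------------------------
  log <- stage_log(log, "simulate", "generating tree-cover rasters")
  r_central <- generate_tree_cover_raster(config$central, seed = seed)
  r_west <- generate_tree_cover_raster(config$west,
                                       seed = substream_seed(seed, "west"))
  # pre-deforestation epoch for the change mask: same world, no patches
  west_t0_spec <- config$west
  west_t0_spec$deforestation_fraction <- 0
  r_west_t0 <- generate_tree_cover_raster(west_t0_spec,
                                          seed = substream_seed(seed, "west"))

  log <- stage_log(log, "gradient", "band means and slope ANCOVA")
  bs_central <- band_means(r_central, config$band_width_km)
  bs_west <- band_means(r_west, config$band_width_km)
  bs_west_fit <- if (config$apply_shift_in_ancova)
    align_regions(bs_west, config$shift_deg) else bs_west
  ancova <- gradient_ancova(bs_west_fit, bs_central)
  defmask <- deforestation_mask(r_west_t0, r_west,
                                config$deforestation_threshold)

  # --- sampling -------------------------------------------------------
  log <- stage_log(log, "simulate", "sampling sites and individuals")
  sites_c <- generate_sites(r_central, config$n_sites$central[["forest"]],
                            config$n_sites$central[["ecotone"]], seed = seed)
  sites_w <- generate_sites(r_west, config$n_sites$west[["forest"]],
                            config$n_sites$west[["ecotone"]],
                            seed = substream_seed(seed, "west_sites"))
  ind_c <- generate_individuals(sites_c, config$model, config$n_per_site,
                                seed = seed)
  ind_w <- generate_individuals(sites_w, config$west_model,
                                config$n_per_site,
                                seed = substream_seed(seed, "west_ind"))
  individuals <- rbind(ind_c, ind_w)
  log <- stage_log(log, "simulate",
                   sprintf("%d contemporary individuals at %d sites",
                           nrow(individuals), nrow(sites_c) + nrow(sites_w)))
  hist_c <- generate_historical_cohort(sites_c, config$model,
                                       n = config$n_historical, seed = seed)
  hist_w <- generate_historical_cohort(sites_w, config$model,
                                       n = config$n_historical,
                                       seed = substream_seed(seed, "west_hist"))
  historical <- filter_historical(rbind(hist_c, hist_w),
                                  config$historical_cutoff)

  # --- morphometrics + screen ----------------------------------------
  log <- stage_log(log, "morpho", "covariance gate, PCA, size correction")
  derived <- derive_traits(individuals)
  pca <- attr(derived, "pca")
  scr <- trait_cover_association_screen(individuals, alpha = config$alpha,
                                        derived = derived)
  log <- stage_log(log, "screen",
                   sprintf("kept: %s; excluded: %s",
                           paste(scr$kept, collapse = ", "),
                           paste(scr$excluded, collapse = ", ")))

  # --- divergence -----------------------------------------------------
  log <- stage_log(log, "diverge", "habitat and era rank-sum tests")
  div_traits <- intersect(DIVERGENCE_TRAITS, scr$kept)
  if (length(div_traits) == 0L) div_traits <- DIVERGENCE_TRAITS
  div_c <- habitat_divergence(individuals, "central", traits = div_traits,
                              alpha = config$alpha, derived = derived)
  div_w <- habitat_divergence(individuals, "west", traits = div_traits,
                              alpha = config$alpha, derived = derived)
  divergence <- rbind(div_c, div_w)
  era_div <- era_divergence(individuals, historical, traits = div_traits,
                            alpha = config$alpha)

  # --- resampling -----------------------------------------------------
  log <- stage_log(log, "resample",
                   sprintf("stratified bootstrap, B = %d", config$B))
  src <- individuals[individuals$region == "central", , drop = FALSE]
  foc <- individuals[individuals$region == "west", , drop = FALSE]
  src_d <- derived[derived$region == "central", , drop = FALSE]
  foc_d <- derived[derived$region == "west", , drop = FALSE]
  boot <- lapply(div_traits, function(tr)
    bootstrap_divergence_test(src, foc, tr, B = config$B, seed = seed,
                              source_values = src_d[[tr]],
                              focal_values = foc_d[[tr]]))
  names(boot) <- div_traits

  # --- projection -----------------------------------------------------
  log <- stage_log(log, "project", "trait-on-cover models and maps")
  proj_trait <- if (length(scr$kept)) scr$kept[[1L]] else "PC1"
  proj_model <- scr$fits[[proj_trait]]
  proj_map <- project_trait(r_central, proj_model,
                            aggregate_km = config$band_width_km)

  result <- list(rasters = list(central = r_central, west = r_west,
                                west_t0 = r_west_t0),
                 band_series = rbind(bs_central, bs_west),
                 ancova = ancova, deforestation = defmask,
                 sites = rbind(sites_c, sites_w),
                 individuals = individuals, historical = historical,
                 pca = pca, screen = scr, divergence = divergence,
                 era_divergence = era_div, bootstrap = boot,
                 projection = list(trait = proj_trait, model = proj_model,
                                   map = proj_map),
                 config = config, log = log)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

# Persist the stage artifacts of a run as plain-text files.
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- function(name) file.path(out_dir, name)
  utils::write.csv(result$sites, wp("sites.csv"), row.names = FALSE)
  utils::write.csv(result$individuals, wp("individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(result$historical, wp("historical.csv"),
                   row.names = FALSE)
  write_band_series(result$band_series, wp("band_series.csv"))
  utils::write.csv(as.data.frame(result$divergence),
                   wp("divergence_contemporary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$era_divergence),
                   wp("divergence_era.csv"), row.names = FALSE)
  write_trait_models(result$screen, wp("trait_models.csv"))
  write_pca_model(result$pca, wp("pca_model.json"))
  write_ascii_grid(result$rasters$central, wp("central_cover.asc"))
  write_ascii_grid(result$rasters$west, wp("west_cover.asc"))
  write_ascii_grid(result$deforestation, wp("west_deforestation_mask.asc"))
  write_ascii_grid(result$projection$map,
                   wp(paste0("projection_", result$projection$trait, ".asc")))
  boot_df <- do.call(rbind, lapply(result$bootstrap, function(b)
    data.frame(trait = b$trait, observed = b$observed_abs_divergence,
               B = b$B, p = b$p, report = b$report,
               stringsAsFactors = FALSE)))
  utils::write.csv(boot_df, wp("bootstrap_tests.csv"), row.names = FALSE)
  nulls <- do.call(cbind, lapply(result$bootstrap, `[[`,
                                 "null_distribution"))
  colnames(nulls) <- names(result$bootstrap)
  utils::write.csv(as.data.frame(nulls), wp("bootstrap_nulls.csv"),
                   row.names = FALSE)
  an <- result$ancova
  writeLines(c(
    "Gradient ANCOVA on band means",
    sprintf("slope[%s] = %.6g", names(an$slopes), an$slopes),
    sprintf("%s: F(%d, %d) = %.6g, p = %.6g", an$table$term, an$table$df,
            an$residual_df, an$table$F, an$table$p)),
    wp("ancova.txt"))
  cfg <- result$config
  jsonlite::write_json(
    list(seed = cfg$seed, band_width_km = cfg$band_width_km,
         shift_deg = cfg$shift_deg,
         deforestation_threshold = cfg$deforestation_threshold,
         B = cfg$B, alpha = cfg$alpha, m = cfg$m,
         historical_cutoff = cfg$historical_cutoff,
         apply_shift_in_ancova = cfg$apply_shift_in_ancova,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("ecotone"))),
    wp("provenance.json"), auto_unbox = TRUE, digits = NA)
  writeLines(result$log, wp("run_log.txt"))
  invisible(out_dir)
}
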