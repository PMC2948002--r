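# Resampling module: the habitat-stratified bootstrap null for the absence
# of rainforest-ecotone divergence, at the individual and population level,
# plus a calibration harness.

# Resolve the analysis-scale values of `trait` for a morphology table:
# derived columns (PC1, wing_sc, ...) are used as-is if present, raw mm
# trait columns are log-transformed, otherwise the derived frame is built.
trait_values <- function(table, trait) {
  if (trait %in% names(table)) {
    v <- table[[trait]]
    if (trait %in% MEASURED_TRAITS) log(v) else v
  } else {
    d <- derive_traits(table)
    if (!trait %in% names(d)) stop("unknown trait: ", trait, call. = FALSE)
    d[[trait]]
  }
}

#' Habitat-stratified bootstrap null distribution of absolute divergence
#'
#' Each of `B` replicates draws, with replacement, `n_forest` individuals
#' from the source region's forest rows and `n_ecotone` from its ecotone
#' rows (the counts are set to those observed in the focal region, so the
#' null mimics the focal sampling design), and records the absolute
#' difference in trait means between the two resampled habitat groups.
#'
#' @param source morphology table for the reference region (must contain
#'   both habitats).
#' @param n_forest,n_ecotone per-habitat draw counts, `>= 1`.
#' @param trait analysis trait (raw mm traits are log-transformed; derived
#'   columns such as `PC1` or `wing_sc` are used as-is if present).
#' @param B number of replicates (default 1000).
#' @param seed integer seed (substream `"bootstrap"`); `(seed, inputs)`
#'   fully determine the output.
#' @param values optional numeric vector of pre-computed trait values
#'   aligned with `source` rows (overrides `trait` lookup).
#' @param identity_resample testing hook: each replicate uses every source
#'   row of each habitat exactly once (no resampling), so with matching
#'   counts the null is degenerate at the observed source divergence.
#' @return A `bootstrap_null`: numeric vector of length `B` with attributes
#'   (`trait`, `counts`, `seed`, `level = "individual"`).
#' @export
stratified_bootstrap_null <- function(source, n_forest, n_ecotone, trait,
                                      B = 1000L, seed = 1L, values = NULL,
                                      identity_resample = FALSE) {
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  if (n_forest < 1L || n_ecotone < 1L)
    stop("per-habitat target counts must be >= 1", call. = FALSE)
  v <- values %||% trait_values(source, trait)
  vf <- v[source$habitat == "forest"]
  ve <- v[source$habitat == "ecotone"]
  if (length(vf) == 0L || length(ve) == 0L)
    stop("source must contain both forest and ecotone rows", call. = FALSE)
  null <- if (identity_resample) {
    rep(abs(mean(vf) - mean(ve)), B)
  } else {
    with_seed(substream_seed(seed, "bootstrap"), {
      fi <- matrix(sample.int(length(vf), B * n_forest, replace = TRUE), B)
      ei <- matrix(sample.int(length(ve), B * n_ecotone, replace = TRUE), B)
      abs(rowMeans(matrix(vf[fi], B)) - rowMeans(matrix(ve[ei], B)))
    })
  }
  structure(null, trait = trait, counts = c(forest = n_forest,
                                            ecotone = n_ecotone),
            seed = seed, level = "individual", class = "bootstrap_null")
}

#' Bootstrap p-value for the absence of divergence
#'
#' The probability of observing a lack of divergence as small as the focal
#' region's: the proportion of null replicates whose absolute divergence is
#' less than or equal to the observed focal value. When no replicate is
#' that small the report string is `"p < 1/B"` (e.g. `"p < 0.001"` at
#' `B = 1000`).
#'
#' @param null numeric null distribution (e.g. from
#'   [stratified_bootstrap_null()]).
#' @param observed observed absolute divergence in the focal region.
#' @return List: `p`, `report` (human-readable string), `B`.
#' @export
bootstrap_p <- function(null, observed) {
  if (length(null) == 0L) stop("empty null distribution", call. = FALSE)
  B <- length(null)
  p <- sum(null <= observed) / B
  report <- if (p == 0) paste0("p < ", format(1 / B))
            else paste0("p = ", format(p))
  list(p = p, report = report, B = B)
}

#' Run the full individual-level bootstrap divergence test
#'
#' Convenience wrapper: computes the focal region's observed absolute
#' divergence, the stratified null from the reference region with matched
#' per-habitat counts, and the bootstrap p-value.
#'
#' @param source reference-region morphology table.
#' @param focal focal-region morphology table (both habitats present).
#' @param trait analysis trait.
#' @param B,seed see [stratified_bootstrap_null()].
#' @param source_values,focal_values optional pre-computed trait values.
#' @return A `bootstrap_result` list: `trait`,
#'   `observed_abs_divergence`, `B`, `null_distribution`, `p`, `report`,
#'   `seed`, `level`.
#' @export
bootstrap_divergence_test <- function(source, focal, trait, B = 1000L,
                                      seed = 1L, source_values = NULL,
                                      focal_values = NULL) {
  fv <- focal_values %||% trait_values(focal, trait)
  xf <- fv[focal$habitat == "forest"]
  xe <- fv[focal$habitat == "ecotone"]
  if (length(xf) == 0L || length(xe) == 0L)
    stop("focal table must contain both habitats", call. = FALSE)
  obs <- abs(mean(xf) - mean(xe))
  null <- stratified_bootstrap_null(source, length(xf), length(xe), trait,
                                    B = B, seed = seed,
                                    values = source_values)
  bp <- bootstrap_p(null, obs)
  structure(list(trait = trait, observed_abs_divergence = obs, B = bp$B,
                 null_distribution = as.numeric(null), p = bp$p,
                 report = bp$report, seed = seed, level = "individual"),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Stratified bootstrap (%s level), trait %s: observed |divergence| = %.4g, B = %d, %s\n",
    x$level, x$trait, x$observed_abs_divergence, x$B, x$report))
  invisible(x)
}

#' Population-level (whole-site) bootstrap null
#'
#' Tests whether an absence of divergence could result from the chance
#' sampling of atypical populations: each replicate resamples, with
#' replacement, whole sites (all of their individuals) to match the focal
#' region's per-habitat site counts, then computes the absolute divergence
#' in trait means between the pooled forest and ecotone individuals.
#'
#' @param source reference-region morphology table with `site_id`.
#' @param site_counts named counts, e.g. `c(forest = 4, ecotone = 3)`.
#' @param trait,B,seed,values as in [stratified_bootstrap_null()].
#' @return A `bootstrap_null` with attribute `level = "population"`.
#' @export
population_bootstrap_null <- function(source, site_counts, trait,
                                      B = 1000L, seed = 1L, values = NULL) {
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  v <- values %||% trait_values(source, trait)
  # shares the "bootstrap" substream with stratified_bootstrap_null so
  # that, when every site holds exactly one individual, the two levels
  # produce identical nulls under the same seed (consistency property)
  for (hab in c("forest", "ecotone"))
    if (!hab %in% names(site_counts) || site_counts[[hab]] < 1L)
      stop("`site_counts` needs a positive count for ", hab, call. = FALSE)
  out <- with_seed(substream_seed(seed, "bootstrap"), {
    pick <- list()
    for (hab in c("forest", "ecotone")) {
      k <- site_counts[[hab]]
      sites <- unique(source$site_id[source$habitat == hab])
      if (length(sites) == 0L)
        stop("habitat ", hab, " absent in source", call. = FALSE)
      vals_by_site <- split(v[source$habitat == hab],
                            source$site_id[source$habitat == hab])
      draws <- matrix(sample(length(sites), B * k, replace = TRUE), B)
      pick[[hab]] <- vapply(seq_len(B), function(b) {
        ind <- unlist(vals_by_site[draws[b, ]], use.names = FALSE)
        mean(ind)
      }, numeric(1L))
    }
    abs(pick$forest - pick$ecotone)
  })
  structure(out, trait = trait, counts = unlist(site_counts), seed = seed,
            level = "population", class = "bootstrap_null")
}

#' Calibration harness for the bootstrap divergence test
#'
#' Simulates `n_sims` focal datasets (and fresh reference pools) from a
#' shared trait generating model, runs the individual-level bootstrap test
#' on each, and reports the fraction of simulations with `p <= alpha`.
#' When focal and reference share the generating process this fraction
#' estimates the test's size; setting `focal_model` to a divergence-free
#' model while the reference keeps a strong habitat contrast estimates its
#' power.
#'
#' @param model reference-region [trait_gen_model()].
#' @param focal_model focal-region model (default: same as `model`).
#' @param trait raw trait to test (its marginal lognormal model is used).
#' @param cover named percent-cover values for the two habitats,
#'   `c(forest = , ecotone = )`.
#' @param n_ref,n_focal named per-habitat individual counts for the
#'   reference pool and the focal sample. Defaults: a large reference pool
#'   (400/200) so that calibration isolates the stratified-resampling
#'   logic from finite-reference noise, and the focal counts 27/11 of the
#'   sparsely sampled region.
#' @param B replicates per test (default 1000).
#' @param n_sims number of simulated datasets (default 500).
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return List: `rejection_rate`, `p_values`, `n_sims`, `B`, `alpha`.
#' @export
calibrate_null <- function(model, focal_model = NULL, trait = "wing",
                           cover = c(forest = 80, ecotone = 30),
                           n_ref = c(forest = 400, ecotone = 200),
                           n_focal = c(forest = 27, ecotone = 11),
                           B = 1000L, n_sims = 500L, alpha = 0.05,
                           seed = 1L) {
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  focal_model <- focal_model %||% model
  ti <- match(trait, model$traits)
  if (is.na(ti)) stop("unknown trait: ", trait, call. = FALSE)
  musd <- function(mod, hab) c(
    mod$log_intercepts[ti] + mod$cover_slopes[ti] * cover[[hab]],
    sqrt(mod$covariance[ti, ti]))
  p_values <- with_seed(substream_seed(seed, "calibration"), {
    vapply(seq_len(n_sims), function(s) {
      ref_f <- stats::rnorm(n_ref[["forest"]], musd(model, "forest")[1L],
                            musd(model, "forest")[2L])
      ref_e <- stats::rnorm(n_ref[["ecotone"]], musd(model, "ecotone")[1L],
                            musd(model, "ecotone")[2L])
      foc_f <- stats::rnorm(n_focal[["forest"]],
                            musd(focal_model, "forest")[1L],
                            musd(focal_model, "forest")[2L])
      foc_e <- stats::rnorm(n_focal[["ecotone"]],
                            musd(focal_model, "ecotone")[1L],
                            musd(focal_model, "ecotone")[2L])
      obs <- abs(mean(foc_f) - mean(foc_e))
      nf <- length(foc_f); ne <- length(foc_e)
      fi <- matrix(sample.int(length(ref_f), B * nf, replace = TRUE), B)
      ei <- matrix(sample.int(length(ref_e), B * ne, replace = TRUE), B)
      null <- abs(rowMeans(matrix(ref_f[fi], B)) -
                    rowMeans(matrix(ref_e[ei], B)))
      sum(null <= obs) / B
    }, numeric(1L))
  })
  list(rejection_rate = mean(p_values <= alpha), p_values = p_values,
       n_sims = n_sims, B = B, alpha = alpha)
}
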