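# Projection module: site-level weighted phenotype-on-tree-cover
# regressions, the trait screen, and raster projection of fitted models.

#' Per-site mean of an analysis trait
#'
#' Aggregates individual values of a derived analysis trait (log mm trait,
#' PC score, or size-corrected residual) to site means with sample sizes
#' and site tree cover -- the unit of the weighted regressions.
#'
#' @param table morphology table (`site_id` and `tree_cover` required).
#' @param trait analysis trait name.
#' @param derived optional pre-computed [derive_traits()] frame.
#' @return Data frame: `site_id, tree_cover, value, n`.
#' @export
site_trait_means <- function(table, trait, derived = NULL) {
  v <- if (!is.null(derived)) derived[[trait]] else trait_values(table, trait)
  agg <- tapply(v, table$site_id, mean)
  ns <- tapply(v, table$site_id, length)
  cov <- tapply(table$tree_cover, table$site_id, function(z) z[1L])
  data.frame(site_id = names(agg), tree_cover = as.numeric(cov),
             value = as.numeric(agg), n = as.integer(ns),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample-size-weighted regression of a trait on percent tree cover
#'
#' Weighted least squares of site mean trait values (log or PC scale) on
#' site percent tree cover, with each site weighted by its sample size.
#' All habitats -- including montane and island sites -- belong in this
#' regression: the phenotype-cover relationship is assumed general.
#'
#' @param site_means data frame from [site_trait_means()] (columns
#'   `tree_cover`, `value`, `n`).
#' @param trait trait label stored on the model.
#' @param transform `"log"` (back-transform by exponentiation when
#'   projecting), `"none"`, or `"pc-score"`.
#' @return A `trait_model`: `trait`, `transform`, `slope`, `intercept`,
#'   `r_squared`, `p` (slope test), `n_sites`, `weight_rule`, `fit`.
#' @export
weighted_trait_regression <- function(site_means, trait,
                                      transform = c("log", "none",
                                                    "pc-score")) {
  transform <- match.arg(transform)
  if (nrow(site_means) < 3L)
    stop("need at least 3 sites", call. = FALSE)
  if (any(site_means$n <= 0)) stop("weights must be > 0", call. = FALSE)
  if (stats::var(site_means$tree_cover) < 1e-12)
    stop("zero tree-cover variance across sites", call. = FALSE)
  fit <- stats::lm(value ~ tree_cover, data = site_means,
                   weights = site_means$n)
  sm <- summary(fit)
  structure(list(trait = trait, transform = transform,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = sm$coefficients[2L, 2L],
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2L, 4L],
                 n_sites = nrow(site_means),
                 weight_rule = "site sample size", fit = fit),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "Weighted regression of %s (%s scale) on %% tree cover:\n  slope = %.5g (SE %.3g), intercept = %.5g, R2 = %.3f, p = %.3g, %d sites\n",
    x$trait, x$transform, x$slope, x$slope_se, x$intercept, x$r_squared,
    x$p, x$n_sites))
  invisible(x)
}

#' Project a fitted trait model over a tree-cover raster
#'
#' Per-pixel prediction `intercept + slope * cover`, block-mean aggregated
#' to `aggregate_km` resolution, then back-transformed by exponentiation
#' for log-scale traits. By default the back-transform follows aggregation
#' (aggregate on the model scale, then exponentiate); set
#' `back_transform = "before"` to exponentiate per pixel first. Partial
#' edge blocks are averaged over their available pixels; nodata propagates
#' (a block that is entirely nodata stays nodata).
#'
#' @param raster a `tree_cover_raster`.
#' @param model a `trait_model`.
#' @param aggregate_km output resolution in km; must be at least the native
#'   resolution.
#' @param back_transform `"after"` (default), `"before"`, or `"none"`.
#' @return An `eco_raster` of predicted trait values.
#' @export
project_trait <- function(raster, model, aggregate_km = 5,
                          back_transform = c("after", "before", "none")) {
  back_transform <- match.arg(back_transform)
  native_km <- raster$cellsize * KM_PER_DEGREE
  if (aggregate_km < native_km - 1e-9)
    stop("`aggregate_km` is below the native resolution (",
         format(native_km), " km)", call. = FALSE)
  k <- max(1L, as.integer(round(aggregate_km / native_km)))
  v <- raster$values
  v[v == raster$nodata] <- NA_real_
  pred <- model$intercept + model$slope * v
  do_exp <- model$transform == "log" && back_transform != "none"
  if (do_exp && back_transform == "before") pred <- exp(pred)
  agg <- block_mean(pred, k)
  if (do_exp && back_transform == "after") agg <- exp(agg)
  agg[is.na(agg)] <- -9999
  tree_cover_raster(agg, raster$xll,
                    # southern edge is preserved; rows aggregate from the top
                    raster$yll + (nrow(v) - nrow(agg) * k) * raster$cellsize,
                    raster$cellsize * k, nodata = -9999,
                    region = raster$region, check_range = FALSE)
}

# Block mean of a matrix with factor k, NA-aware; partial trailing blocks
# are averaged over available cells.
block_mean <- function(m, k) {
  if (k == 1L) return(m)
  nr <- ceiling(nrow(m) / k)
  nc <- ceiling(ncol(m) / k)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- ((i - 1L) * k + 1L):min(i * k, nrow(m))
    for (j in seq_len(nc)) {
      cj <- ((j - 1L) * k + 1L):min(j * k, ncol(m))
      blk <- m[ri, cj]
      if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
    }
  }
  out
}

#' Screen traits for a significant association with tree cover
#'
#' Fits the sample-size-weighted trait-on-cover regression for every
#' candidate trait and partitions them into kept (slope `p <= alpha`) and
#' excluded; only kept traits enter divergence testing and projection.
#' Typical outcome on this system: PC2 and upper mandible length drop out.
#'
#' @param table morphology table covering all sites (all habitats).
#' @param traits candidate derived trait names (default: PC1, PC2, the four
#'   log traits, and size-corrected wing/tail).
#' @param alpha screen level (default 0.05).
#' @param derived optional pre-computed [derive_traits()] frame.
#' @return List: `kept`, `excluded`, and `models` (a data frame with slope,
#'   R-squared and p per candidate).
#' @export
trait_cover_association_screen <- function(table,
                                           traits = c("PC1", "PC2",
                                                      "tarsus", "wing",
                                                      "tail",
                                                      "upper_mandible",
                                                      "wing_sc", "tail_sc"),
                                           alpha = 0.05, derived = NULL) {
  if (length(traits) == 0L)
    return(list(kept = character(), excluded = character(),
                models = data.frame()))
  d <- derived %||% derive_traits(table)
  fits <- lapply(traits, function(tr) {
    sm <- site_trait_means(table, tr, derived = d)
    weighted_trait_regression(
      sm, tr,
      transform = if (tr %in% MEASURED_TRAITS) "log" else "pc-score")
  })
  models <- data.frame(
    trait = traits,
    slope = vapply(fits, `[[`, numeric(1L), "slope"),
    r_squared = vapply(fits, `[[`, numeric(1L), "r_squared"),
    p = vapply(fits, `[[`, numeric(1L), "p"),
    n_sites = vapply(fits, `[[`, integer(1L), "n_sites"),
    kept = vapply(fits, function(f) f$p <= alpha, logical(1L)),
    stringsAsFactors = FALSE)
  list(kept = models$trait[models$kept],
       excluded = models$trait[!models$kept],
       models = models, fits = stats::setNames(fits, traits))
}

#' Export fitted trait models as a CSV table
#' @param screen result of [trait_cover_association_screen()].
#' @param path output CSV path.
#' @export
write_trait_models <- function(screen, path) {
  utils::write.csv(screen$models, path, row.names = FALSE)
  invisible(path)
}
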