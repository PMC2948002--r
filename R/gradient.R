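# Gradient module: latitudinal band means, region alignment, the
# slope-difference ANCOVA, and the deforestation change mask.

#' Mean tree cover per latitudinal band
#'
#' Latitude is partitioned into half-open bands `[low, high)` of width
#' `band_width_km / 111.32` degrees anchored at the raster's southern edge;
#' each band's value is the arithmetic mean over its non-nodata pixels.
#' Bands with no usable pixel are omitted, so the result always satisfies
#' `n_pixels >= 1`.
#'
#' @param raster a `tree_cover_raster`.
#' @param band_width_km band width in km (default 5, the unit of the
#'   gradient plots).
#' @return A `band_series` data frame: `region, band_center_lat, mean_cover,
#'   n_pixels, shifted, shift_deg`.
#' @export
band_means <- function(raster, band_width_km = 5) {
  if (band_width_km <= 0) stop("`band_width_km` must be > 0", call. = FALSE)
  width <- band_width_km / KM_PER_DEGREE
  lat <- raster_lat_centers(raster)
  band <- floor((lat - raster$yll) / width)      # per row; rows share lat
  v <- raster$values
  v[v == raster$nodata] <- NA_real_
  sums <- rowSums(v, na.rm = TRUE)
  ns <- rowSums(!is.na(v))
  agg_sum <- tapply(sums, band, sum)
  agg_n <- tapply(ns, band, sum)
  keep <- agg_n >= 1
  if (!any(keep)) stop("raster is entirely nodata", call. = FALSE)
  idx <- as.numeric(names(agg_sum))[keep]
  out <- data.frame(
    region = raster$region %||% NA_character_,
    band_center_lat = raster$yll + (idx + 0.5) * width,
    mean_cover = as.numeric(agg_sum[keep] / agg_n[keep]),
    n_pixels = as.integer(agg_n[keep]),
    shifted = FALSE, shift_deg = 0,
    stringsAsFactors = FALSE)
  out <- out[order(out$band_center_lat), ]
  rownames(out) <- NULL
  class(out) <- c("band_series", "data.frame")
  out
}

#' Shift a band series southward to align gradient positions across regions
#'
#' Decrements every band center by `shift_deg` (positive = southward) and
#' flags the series as shifted; mean cover is untouched. Used to align the
#' latitudinal position of the rainforest-ecotone boundary between regions
#' before plotting or fitting.
#'
#' @param series a `band_series`.
#' @param shift_deg degrees to subtract from each band center.
#' @return The shifted `band_series`.
#' @export
align_regions <- function(series, shift_deg) {
  series$band_center_lat <- series$band_center_lat - shift_deg
  series$shifted <- series$shifted | shift_deg != 0
  series$shift_deg <- series$shift_deg + shift_deg
  series
}

#' ANCOVA for region-dependent gradient slope
#'
#' Ordinary least squares of `mean_cover ~ region + latitude +
#' region:latitude` on the band means of two regions. The interaction term
#' tests whether the tree-cover-by-latitude slope differs between regions,
#' i.e. whether one gradient is flatter. F statistics are sequential
#' (type I, interaction fitted last, so its F is the partial F).
#'
#' @param series_a,series_b `band_series` for the two regions (at least 3
#'   bands each, distinct region labels).
#' @return An `ancova_result`: per-region slopes and intercepts, the ANOVA
#'   table (`region`, `latitude`, `region:latitude` with F and p), residual
#'   dof, the fitted `lm`, and the unit of analysis (`"band_means"`).
#' @export
gradient_ancova <- function(series_a, series_b) {
  for (s in list(series_a, series_b))
    if (nrow(s) < 3L)
      stop("need at least 3 bands per region", call. = FALSE)
  dat <- rbind(as.data.frame(series_a), as.data.frame(series_b))
  dat$region <- factor(dat$region)
  if (nlevels(dat$region) != 2L)
    stop("the two series must carry distinct region labels", call. = FALSE)
  if (any(tapply(dat$band_center_lat, dat$region, stats::var) < 1e-12))
    stop("zero latitude variance within a region", call. = FALSE)
  fit <- stats::lm(mean_cover ~ region * band_center_lat, data = dat)
  an <- stats::anova(fit)
  co <- stats::coef(fit)
  lev <- levels(dat$region)
  slopes <- c(co[["band_center_lat"]],
              co[["band_center_lat"]] +
                co[[paste0("region", lev[2L], ":band_center_lat")]])
  intercepts <- c(co[[1L]], co[[1L]] + co[[paste0("region", lev[2L])]])
  names(slopes) <- names(intercepts) <- lev
  tab <- data.frame(
    term = c("region", "latitude", "region:latitude"),
    df = an$Df[1:3], F = an$`F value`[1:3], p = an$`Pr(>F)`[1:3],
    stringsAsFactors = FALSE)
  structure(list(slopes = slopes, intercepts = intercepts,
                 coefficients = co, table = tab,
                 residual_df = an$Df[4L], fit = fit,
                 unit = "band_means",
                 shifted = unique(dat$shift_deg)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("Gradient ANCOVA on", x$unit, "\n")
  cat(sprintf("  slopes (%% cover / deg lat): %s\n",
              paste(sprintf("%s = %.3f", names(x$slopes), x$slopes),
                    collapse = ", ")))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-16s F(%d, %d) = %.2f, p = %.3g\n", x$table$term[i],
                x$table$df[i], x$residual_df, x$table$F[i], x$table$p[i]))
  invisible(x)
}

#' Mask of recent deforestation between two epochs
#'
#' A pixel is masked when cover dropped *strictly more than*
#' `threshold_pct` between the two epochs (`t0` earlier, `t1` later); a
#' drop of exactly the threshold is not masked. Nodata in either epoch
#' propagates. Rasters must share a grid unless `resample = TRUE`, in which
#' case `t1` is resampled to `t0`'s grid by nearest neighbour.
#'
#' @param cover_t0,cover_t1 `tree_cover_raster`s for the two epochs.
#' @param threshold_pct percent-cover drop threshold (default 10).
#' @param resample allow nearest-neighbour re-gridding of `cover_t1`.
#' @return An `eco_raster` with values 1 (deforested), 0, or nodata.
#' @export
deforestation_mask <- function(cover_t0, cover_t1, threshold_pct = 10,
                               resample = FALSE) {
  same_grid <- identical(dim(cover_t0$values), dim(cover_t1$values)) &&
    isTRUE(all.equal(c(cover_t0$xll, cover_t0$yll, cover_t0$cellsize),
                     c(cover_t1$xll, cover_t1$yll, cover_t1$cellsize)))
  if (!same_grid) {
    if (!resample)
      stop("rasters are not co-registered; set `resample = TRUE` for ",
           "nearest-neighbour re-gridding", call. = FALSE)
    cover_t1 <- resample_nearest(cover_t1, cover_t0)
  }
  v0 <- cover_t0$values
  v1 <- cover_t1$values
  bad <- v0 == cover_t0$nodata | v1 == cover_t1$nodata
  m <- (v0 - v1) > threshold_pct
  out <- ifelse(bad, -1, as.numeric(m))
  tree_cover_raster(out, cover_t0$xll, cover_t0$yll, cover_t0$cellsize,
                    nodata = -1, region = cover_t0$region,
                    check_range = FALSE)
}

# Nearest-neighbour resampling of `src` onto `target`'s grid.
resample_nearest <- function(src, target) {
  tlat <- raster_lat_centers(target)
  tlon <- raster_lon_centers(target)
  nr_s <- nrow(src$values); nc_s <- ncol(src$values)
  ri <- nr_s - floor((tlat - src$yll) / src$cellsize)
  ci <- floor((tlon - src$xll) / src$cellsize) + 1L
  vals <- matrix(src$nodata, length(tlat), length(tlon))
  ok_r <- ri >= 1L & ri <= nr_s
  ok_c <- ci >= 1L & ci <= nc_s
  vals[ok_r, ok_c] <- src$values[ri[ok_r], ci[ok_c], drop = FALSE]
  tree_cover_raster(vals, target$xll, target$yll, target$cellsize,
                    nodata = src$nodata, region = src$region,
                    epoch = src$epoch, check_range = FALSE)
}

#' Write a band series to CSV
#' @param series a `band_series`.
#' @param path output path.
#' @export
write_band_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a band series from CSV
#' @param path CSV written by [write_band_series()].
#' @export
read_band_series <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("band_series", "data.frame")
  out
}
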