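# Synthetic-data module: tree-cover rasters, field sites, and morphology
# tables with the statistical structure the downstream analysis assumes.
#
# The generator states a world and sticks to it: a linear latitudinal
# tree-cover trend per region plus i.i.d. pixel noise and Bernoulli
# deforestation patches; individuals whose log-trait means are linear in
# site tree cover, with region-specific trait covariance matrices that are
# equal, proportional, or unrelated by configuration.

#' Region specification for the synthetic tree-cover raster
#'
#' @param name region label (e.g. `"west"`, `"central"`).
#' @param lat_range,lon_range numeric length-2, degrees, min < max.
#' @param cover_intercept percent tree cover at the southern edge
#'   (reference latitude = `lat_range[1]`).
#' @param cover_slope percent cover per degree latitude (negative =
#'   cover decreases northward, the rainforest-to-savanna direction).
#' @param noise_sd per-pixel Gaussian noise, percent.
#' @param deforestation_fraction proportion of pixels in `[0, 1]` hit by a
#'   deforestation patch.
#' @param deforestation_depth percent cover removed from deforested pixels.
#' @return A `region_spec` list.
#' @export
region_spec <- function(name, lat_range, lon_range,
                        cover_intercept, cover_slope,
                        noise_sd = 0, deforestation_fraction = 0,
                        deforestation_depth = 0) {
  stopifnot(length(lat_range) == 2L, length(lon_range) == 2L)
  if (deforestation_fraction < 0 || deforestation_fraction > 1)
    stop("`deforestation_fraction` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(name = name, lat_range = as.numeric(lat_range),
                 lon_range = as.numeric(lon_range),
                 cover_intercept = cover_intercept,
                 cover_slope = cover_slope, noise_sd = noise_sd,
                 deforestation_fraction = deforestation_fraction,
                 deforestation_depth = deforestation_depth),
            class = "region_spec")
}

#' Generating model for individual morphology
#'
#' Log-trait means are linear in site percent tree cover; individuals are
#' multivariate normal on the log scale (so all traits are lognormal in
#' mm, and the downstream log-log size-correction regressions are exactly
#' linear in expectation). The second region's covariance can be scaled by
#' `region_scale` (1 = equal matrices, otherwise proportional) or replaced
#' wholesale via `region_covariance` (unrelated).
#'
#' @param traits trait names; defaults to the four measured traits.
#' @param log_intercepts per-trait log-mm at 0% cover.
#' @param cover_slopes per-trait log-mm change per percent cover.
#' @param covariance trait x trait covariance on the log scale (symmetric
#'   positive definite).
#' @param region_scale positive scalar multiplying `covariance` for
#'   `scaled_region`.
#' @param scaled_region region label the scaling applies to (default none).
#' @param region_covariance optional full replacement covariance for
#'   `scaled_region` (overrides `region_scale`).
#' @return A `trait_gen_model` list.
#' @export
trait_gen_model <- function(traits = c("tarsus", "wing", "tail",
                                       "upper_mandible"),
                            log_intercepts, cover_slopes, covariance,
                            region_scale = 1, scaled_region = NA_character_,
                            region_covariance = NULL) {
  p <- length(traits)
  stopifnot(length(log_intercepts) == p, length(cover_slopes) == p)
  if (!is_symmetric_pd(covariance))
    stop("`covariance` must be symmetric positive definite", call. = FALSE)
  if (region_scale <= 0) stop("`region_scale` must be > 0", call. = FALSE)
  if (!is.null(region_covariance) && !is_symmetric_pd(region_covariance))
    stop("`region_covariance` must be symmetric positive definite",
         call. = FALSE)
  structure(list(traits = traits,
                 log_intercepts = stats::setNames(log_intercepts, traits),
                 cover_slopes = stats::setNames(cover_slopes, traits),
                 covariance = covariance, region_scale = region_scale,
                 scaled_region = scaled_region,
                 region_covariance = region_covariance),
            class = "trait_gen_model")
}

#' Default morphology generating model
#'
#' Trait scales are those of a small greenbul-like passerine (tarsus ~20 mm,
#' wing ~63 mm, tail ~57 mm, upper mandible ~14 mm); log-scale SD 0.05
#' (coefficient of variation ~5%) with exchangeable correlation 0.5, the
#' regime where overall size dominates PC1. Cover slopes are negative (birds
#' larger in low-cover ecotone habitat): over a forest-to-ecotone contrast of
#' 50 percentage points they move wing and tail by ~12% and tarsus by ~7%,
#' comparable to reported rainforest-ecotone contrasts in this system.
#'
#' @param region_scale,scaled_region,region_covariance see
#'   [trait_gen_model()].
#' @param cover_slopes optionally override the per-trait slopes.
#' @return A `trait_gen_model`.
#' @export
default_trait_model <- function(region_scale = 1,
                                scaled_region = NA_character_,
                                region_covariance = NULL,
                                cover_slopes = NULL) {
  traits <- c("tarsus", "wing", "tail", "upper_mandible")
  sd_log <- 0.05
  R <- matrix(0.5, 4, 4); diag(R) <- 1
  sigma <- R * sd_log^2
  dimnames(sigma) <- list(traits, traits)
  # upper mandible tracks diet, not tree cover: slope 0, so the screen
  # excludes it (with PC2) just as in the real system
  slopes <- cover_slopes %||% c(tarsus = -0.0015, wing = -0.0025,
                                tail = -0.0025, upper_mandible = 0)
  # intercepts chosen so mid-gradient (cover 50) means sit at typical values
  mids <- c(tarsus = 20, wing = 63, tail = 57, upper_mandible = 14)
  trait_gen_model(traits, log(mids) - slopes * 50, slopes, sigma,
                  region_scale = region_scale, scaled_region = scaled_region,
                  region_covariance = region_covariance)
}

#' Generate a synthetic percent-tree-cover raster
#'
#' Pixel value = `clip(intercept + slope * (lat - lat_min) + N(0, noise_sd),
#' 0, 100)`; afterwards a Bernoulli(`deforestation_fraction`) subset of
#' pixels is reduced by `deforestation_depth` (clipped at 0). The noise-free,
#' pre-deforestation trend is attached as attribute `"potential"` and stands
#' in for the potential-forest (IGBP-style) layer: habitat labels downstream
#' depend only on it, never on realized noise or deforestation.
#'
#' @param spec a [region_spec()].
#' @param resolution_km pixel size in km (1 degree = 111.32 km).
#' @param seed integer; the `"raster"` substream of this seed drives all
#'   randomness, so identical seeds give identical rasters.
#' @return A `tree_cover_raster`.
#' @export
generate_tree_cover_raster <- function(spec, resolution_km = 5, seed = 1) {
  if (resolution_km <= 0) stop("`resolution_km` must be > 0", call. = FALSE)
  deg <- resolution_km / KM_PER_DEGREE
  nr <- floor(diff(spec$lat_range) / deg)
  nc <- floor(diff(spec$lon_range) / deg)
  if (nr < 1L || nc < 1L)
    stop("empty extent: lat/lon range smaller than one pixel", call. = FALSE)
  yll <- spec$lat_range[1L]
  lat <- yll + deg * (nr - seq_len(nr) + 0.5)       # row centers, N -> S
  trend_row <- spec$cover_intercept +
    spec$cover_slope * (lat - spec$lat_range[1L])
  trend <- matrix(trend_row, nrow = nr, ncol = nc)
  potential <- pmin(pmax(trend, 0), 100)
  vals <- with_seed(substream_seed(seed, "raster"), {
    v <- trend
    if (spec$noise_sd > 0)
      v <- v + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    v <- pmin(pmax(v, 0), 100)
    if (spec$deforestation_fraction > 0) {
      hit <- matrix(stats::runif(nr * nc) < spec$deforestation_fraction,
                    nr, nc)
      v[hit] <- pmax(v[hit] - spec$deforestation_depth, 0)
    }
    v
  })
  r <- tree_cover_raster(vals, xll = spec$lon_range[1L], yll = yll,
                         cellsize = deg, region = spec$name)
  attr(r, "potential") <- potential
  r
}

#' Sample field sites from a raster
#'
#' Habitat labels follow the potential-forest convention: a site is `forest`
#' if the *potential* (pre-deforestation trend) cover at its pixel reaches
#' `habitat_rule$forest_min`, even when realized cover is ecotone-like --
#' deforested potential-forest sites remain forest sites. `ecotone` pixels
#' have potential cover in `[habitat_rule$ecotone_range)`.
#'
#' @param raster a raster from [generate_tree_cover_raster()] (must carry
#'   the `"potential"` attribute, or pass one via `potential`).
#' @param n_forest,n_ecotone site counts per habitat.
#' @param habitat_rule list with `forest_min` (default 60) and
#'   `ecotone_range` (default `c(20, 60)`), percent potential cover.
#' @param seed integer seed (substream `"sites"`).
#' @param potential optional potential-cover matrix overriding the attribute.
#' @return A site table: `site_id, lon, lat, region, habitat, tree_cover,
#'   row, col`.
#' @export
generate_sites <- function(raster, n_forest, n_ecotone,
                           habitat_rule = list(forest_min = 60,
                                               ecotone_range = c(20, 60)),
                           seed = 1, potential = NULL) {
  pot <- potential %||% attr(raster, "potential")
  if (is.null(pot))
    stop("raster carries no potential-forest layer; supply `potential`",
         call. = FALSE)
  fmin <- habitat_rule$forest_min %||% 60
  erng <- habitat_rule$ecotone_range %||% c(20, fmin)
  ok <- raster$values != raster$nodata
  forest_idx <- which(pot >= fmin & ok)
  ecotone_idx <- which(pot >= erng[1L] & pot < erng[2L] & ok)
  if (length(forest_idx) < n_forest)
    stop("insufficient eligible forest pixels", call. = FALSE)
  if (length(ecotone_idx) < n_ecotone)
    stop("insufficient eligible ecotone pixels", call. = FALSE)
  pick <- with_seed(substream_seed(seed, "sites"), list(
    f = if (n_forest > 0) sample(forest_idx, n_forest) else integer(),
    e = if (n_ecotone > 0) sample(ecotone_idx, n_ecotone) else integer()))
  idx <- c(pick$f, pick$e)
  habitat <- rep(c("forest", "ecotone"), c(n_forest, n_ecotone))
  rc <- arrayInd(idx, dim(raster$values))
  lat <- raster_lat_centers(raster)[rc[, 1L]]
  lon <- raster_lon_centers(raster)[rc[, 2L]]
  data.frame(
    site_id = paste0(raster$region, "_",
                     ifelse(habitat == "forest", "F", "E"),
                     c(seq_len(n_forest), seq_len(n_ecotone))),
    lon = lon, lat = lat,
    region = raster$region %||% NA_character_,
    habitat = habitat,
    tree_cover = raster$values[idx],
    potential_cover = pot[idx],
    row = rc[, 1L], col = rc[, 2L],
    stringsAsFactors = FALSE)
}

trait_means_at <- function(model, cover) {
  model$log_intercepts + model$cover_slopes * cover
}

region_sigma <- function(model, region) {
  if (!is.na(model$scaled_region) && identical(region, model$scaled_region)) {
    if (!is.null(model$region_covariance)) return(model$region_covariance)
    return(model$covariance * model$region_scale)
  }
  model$covariance
}

#' Generate individual morphology measurements at sites
#'
#' Each individual's log-traits are multivariate normal with mean
#' `log_intercepts + cover_slopes * site_cover` and the region's covariance;
#' traits are reported in mm (exponentiated). Collection years are drawn
#' from the contemporary sampling window 1993-2001.
#'
#' @param sites site table from [generate_sites()].
#' @param model a [trait_gen_model()].
#' @param n_per_site single count, or named integer vector by `site_id`.
#' @param seed integer seed (substream `"individuals"`).
#' @return A morphology table: `individual_id, site_id, region, habitat,
#'   era, collection_year, tree_cover`, plus one mm column per trait.
#' @export
generate_individuals <- function(sites, model, n_per_site, seed = 1) {
  if (is.null(names(n_per_site))) {
    if (length(n_per_site) != 1L)
      stop("`n_per_site` must be a single count or named by site_id",
           call. = FALSE)
    n_per_site <- stats::setNames(rep.int(n_per_site, nrow(sites)),
                                  sites$site_id)
  }
  n_per_site <- n_per_site[sites$site_id]
  n_per_site[is.na(n_per_site)] <- 0L
  if (any(n_per_site < 0)) stop("site counts must be >= 0", call. = FALSE)
  with_seed(substream_seed(seed, "individuals"), {
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      n <- n_per_site[i]
      if (n == 0L) return(NULL)
      s <- sites[i, ]
      logs <- rmvnorm_chol(n, trait_means_at(model, s$tree_cover),
                           region_sigma(model, s$region))
      out <- data.frame(site_id = s$site_id, region = s$region,
                        habitat = s$habitat, era = "contemporary",
                        collection_year = sample(1993:2001, n, replace = TRUE),
                        tree_cover = s$tree_cover, stringsAsFactors = FALSE)
      cbind(out, stats::setNames(as.data.frame(exp(logs)), model$traits))
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) stop("no individuals requested", call. = FALSE)
    tab <- cbind(individual_id = sprintf("ind_%04d", seq_len(nrow(tab))), tab,
                 stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    tab
  })
}

#' Generate a historical (museum) cohort
#'
#' Emulates a pre-deforestation museum series: rainforest sites only (the
#' museum record holds almost no ecotone specimens), collection years
#' strictly before 1935, and per-trait log-scale offsets `era_shift` added
#' to the generating means (0 = the pre-shift world equals the contemporary
#' model).
#'
#' Historical individuals are generated at each site's *potential* cover
#' (column `potential_cover`, if present) rather than its realized cover:
#' museum specimens sampled the gradient before deforestation.
#'
#' @param sites site table; only `habitat == "forest"` rows are used.
#' @param model a [trait_gen_model()].
#' @param era_shift per-trait log offsets (scalar recycled across traits).
#' @param n total number of historical individuals (`>= 1`), allocated
#'   round-robin across forest sites.
#' @param seed integer seed (substream `"historical"`).
#' @return A morphology table with `era = "historical"` and
#'   `collection_year < 1935`.
#' @export
generate_historical_cohort <- function(sites, model, era_shift = 0, n,
                                       seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  fs <- sites[sites$habitat == "forest", , drop = FALSE]
  if (nrow(fs) == 0L) stop("no forest sites available", call. = FALSE)
  shift <- rep_len(era_shift, length(model$traits))
  alloc <- tabulate(rep_len(seq_len(nrow(fs)), n), nbins = nrow(fs))
  with_seed(substream_seed(seed, "historical"), {
    rows <- lapply(seq_len(nrow(fs)), function(i) {
      if (alloc[i] == 0L) return(NULL)
      s <- fs[i, ]
      cov_hist <- if (!is.null(s$potential_cover)) s$potential_cover
                  else s$tree_cover
      logs <- rmvnorm_chol(alloc[i],
                           trait_means_at(model, cov_hist) + shift,
                           region_sigma(model, s$region))
      out <- data.frame(site_id = s$site_id, region = s$region,
                        habitat = s$habitat, era = "historical",
                        collection_year = sample(1895:1934, alloc[i],
                                                 replace = TRUE),
                        tree_cover = cov_hist, stringsAsFactors = FALSE)
      cbind(out, stats::setNames(as.data.frame(exp(logs)), model$traits))
    })
    tab <- do.call(rbind, rows)
    tab <- cbind(individual_id = sprintf("hist_%04d", seq_len(nrow(tab))),
                 tab, stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    tab
  })
}
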