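# Morphometrics module: log transforms, allometric size correction,
# covariance-structure tests across regions (the gate for pooling), and
# principal components of the trait covariance matrix.

MEASURED_TRAITS <- c("tarsus", "wing", "tail", "upper_mandible")

#' Allometric size correction by log-log residuals
#'
#' Residuals from an ordinary least-squares regression of `log(trait)` on
#' `log(tarsus)` (tarsus length being the standard body-size proxy).
#' Upper mandible length is never size-corrected: feeding performance
#' depends on absolute bill dimensions, so requesting it is an error.
#' The slope p-value is returned so callers can skip size-corrected
#' analyses when the allometric regression is not significant (the typical
#' situation for small historical series).
#'
#' @param table a morphology table with mm trait columns.
#' @param trait trait to correct (`"wing"` or `"tail"`).
#' @return List: `residuals` (input order), `slope`, `intercept`,
#'   `p_value` (slope t-test), `r_squared`, `n`.
#' @export
size_correct <- function(table, trait) {
  if (trait %in% c("tarsus", "upper_mandible"))
    stop("`", trait, "` is not size-corrected", call. = FALSE)
  if (!trait %in% names(table)) stop("unknown trait: ", trait, call. = FALSE)
  if (nrow(table) < 3L)
    stop("size correction needs at least 3 individuals", call. = FALSE)
  y <- log(table[[trait]])
  x <- log(table$tarsus)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(residuals = as.numeric(stats::resid(fit)),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = sm$coefficients[2L, 4L],
       r_squared = sm$r.squared,
       n = nrow(table))
}

#' Equality and proportionality tests for two region covariance matrices
#'
#' Likelihood-ratio tests on the lower levels of the Flury hierarchy of
#' covariance structures, used to decide whether trait data from two
#' regions may be pooled into a single PCA. With MLE covariances
#' `S1`, `S2` (divisor n) and `Sp` the pooled MLE:
#'
#' * equality (`Sigma1 = Sigma2`): Box's M -- the likelihood-ratio
#'   statistic on unbiased covariance estimates, rescaled by Box's
#'   small-sample factor so the chi-squared reference holds at realistic
#'   field sample sizes (the uncorrected statistic is anti-conservative
#'   below a few hundred individuals per region and would spuriously close
#'   the pooling gate); dof `p(p+1)/2`;
#' * proportionality (`Sigma2 = rho * Sigma1`): `rho` and the common matrix
#'   are estimated by the ML fixed-point iteration
#'   `Sigma <- (n1 S1 + n2 S2 / rho)/n`, `rho <- tr(Sigma^{-1} S2)/p`,
#'   iterated to relative tolerance 1e-10 (max 200 iterations);
#'   `-2 log L = n1 (log|Sigma| - log|S1|) + n2 (log|rho Sigma| - log|S2|)`,
#'   dof `p(p+1)/2 - 1`.
#'
#' Both statistics are referred to chi-squared. The verdict is sequential at
#' `alpha`: `equal` if equality is not rejected; otherwise `proportional` if
#' proportionality is not rejected; otherwise `neither` (pooling refused).
#'
#' @param x1,x2 numeric matrices of log-scale traits (rows = individuals),
#'   same columns; each must have more rows than columns.
#' @param alpha significance level for the sequential verdict.
#' @param dof optional length-2 Wishart degrees of freedom for the two
#'   scatter matrices. Default `c(n1 - 1, n2 - 1)` (one grand mean
#'   estimated per region); when rows were centered within `s` sites,
#'   pass `n - s` per region so the reference distributions stay
#'   calibrated.
#' @return A `cov_struct_result`: both LRTs (statistic, dof, p), the
#'   proportionality constant `rho` (scale of region 2 relative to region
#'   1), and the verdict.
#' @export
covariance_structure_test <- function(x1, x2, alpha = 0.05, dof = NULL) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  p <- ncol(x1)
  if (ncol(x2) != p) stop("trait sets differ between regions", call. = FALSE)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 <= p || n2 <= p)
    stop("each region needs n > number of traits", call. = FALSE)
  v1 <- if (is.null(dof)) n1 - 1 else dof[1L]
  v2 <- if (is.null(dof)) n2 - 1 else dof[2L]
  if (v1 <= p || v2 <= p)
    stop("each region needs dof > number of traits", call. = FALSE)
  vp <- v1 + v2
  # scatter matrices normalized by their Wishart dof
  A1 <- stats::cov(x1) * (n1 - 1); A2 <- stats::cov(x2) * (n2 - 1)
  S1 <- A1 / v1; S2 <- A2 / v2
  if (!is_symmetric_pd(S1) || !is_symmetric_pd(S2))
    stop("singular sample covariance matrix", call. = FALSE)

  # Box's M with the small-sample scale correction (k = 2 groups)
  Sp <- (v1 * S1 + v2 * S2) / vp
  M <- vp * log_det(Sp) - v1 * log_det(S1) - v2 * log_det(S2)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1)) *
    (1 / v1 + 1 / v2 - 1 / vp)
  stat_eq <- M * (1 - c1)
  df_eq <- p * (p + 1) / 2
  p_eq <- stats::pchisq(stat_eq, df_eq, lower.tail = FALSE)

  rho <- sum(diag(solve(S1, S2))) / p   # moment start
  for (it in seq_len(200L)) {
    Sg <- (v1 * S1 + v2 * S2 / rho) / vp
    rho_new <- sum(diag(solve(Sg, S2))) / p
    if (abs(rho_new - rho) / rho < 1e-10) { rho <- rho_new; break }
    rho <- rho_new
  }
  Sg <- (v1 * S1 + v2 * S2 / rho) / vp
  stat_prop <- v1 * (log_det(Sg) - log_det(S1)) +
    v2 * (log_det(rho * Sg) - log_det(S2))
  stat_prop <- max(stat_prop, 0)
  df_prop <- p * (p + 1) / 2 - 1
  p_prop <- stats::pchisq(stat_prop, df_prop, lower.tail = FALSE)

  verdict <- if (p_eq >= alpha) "equal"
             else if (p_prop >= alpha) "proportional"
             else "neither"
  structure(list(
    lrt_equality = list(statistic = stat_eq, dof = df_eq, p = p_eq),
    lrt_proportionality = list(statistic = stat_prop, dof = df_prop,
                               p = p_prop),
    proportionality_constant = rho,
    verdict = verdict, alpha = alpha, n = c(n1, n2), p_traits = p),
    class = "cov_struct_result")
}

#' @export
print.cov_struct_result <- function(x, ...) {
  cat(sprintf("Covariance structure (n = %d, %d; %d traits)\n",
              x$n[1L], x$n[2L], x$p_traits))
  cat(sprintf("  equality:        X2(%g) = %.3f, p = %.4g\n",
              x$lrt_equality$dof, x$lrt_equality$statistic,
              x$lrt_equality$p))
  cat(sprintf("  proportionality: X2(%g) = %.3f, p = %.4g (rho = %.3f)\n",
              x$lrt_proportionality$dof, x$lrt_proportionality$statistic,
              x$lrt_proportionality$p, x$proportionality_constant))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Principal components of log-transformed traits
#'
#' Eigendecomposition of the covariance matrix of log traits; PC1 indexes
#' overall size and PC2 shape. When the table spans two regions the
#' covariance-structure gate is applied first: pooling is refused (unless
#' `override = TRUE`) if the region covariance matrices are neither equal
#' nor proportional. PC signs are fixed deterministically -- the tarsus
#' loading on PC1 is positive (larger PC1 = larger bird), and every other
#' PC has its largest-magnitude loading positive.
#'
#' The gate compares *individual-level* covariance structure: when the
#' table has a `site_id` column (override with `gate_center_by`), traits
#' are centered within sites before the covariance test, so that
#' between-site environmental mean structure -- which legitimately differs
#' between a steep-gradient and a flattened-gradient region -- does not
#' masquerade as a difference in trait covariance. The PCA itself is
#' always computed on the uncentered pooled data (between-site size
#' variation is part of the signal PC1 must carry).
#'
#' @param table morphology table with mm trait columns.
#' @param traits traits entering the PCA (default all four).
#' @param check_covariance apply the gate when > 1 region present.
#' @param override pool even when the verdict is `neither`.
#' @param alpha gate significance level.
#' @param gate_center_by column used to center traits for the gate test
#'   only (default `"site_id"` when present; `NULL` disables centering).
#' @param scope optional era/scope label stored on the model.
#' @return A `pca_model`: `traits`, `center` (log-scale means), `loadings`
#'   (orthonormal columns), `eigenvalues` (non-increasing), `scores`
#'   (one row per individual, in input order), `cov_test`, `scope`.
#' @export
pooled_pca <- function(table, traits = MEASURED_TRAITS,
                       check_covariance = TRUE, override = FALSE,
                       alpha = 0.05, gate_center_by = "site_id",
                       scope = NA_character_) {
  X <- log(as.matrix(table[, traits, drop = FALSE]))
  cov_test <- NULL
  regions <- unique(table$region)
  if (check_covariance && length(regions) == 2L) {
    Xg <- X
    center_groups <- !is.null(gate_center_by) &&
      gate_center_by %in% names(table)
    if (center_groups) {
      grp <- table[[gate_center_by]]
      for (g in unique(grp)) {
        i <- grp == g
        Xg[i, ] <- sweep(Xg[i, , drop = FALSE], 2L,
                         colMeans(Xg[i, , drop = FALSE]))
      }
    }
    by_region <- split.data.frame(Xg, table$region)
    ns <- vapply(by_region, nrow, 1L)
    # dof lost to mean estimation: one per centering group, else one
    constraints <- if (center_groups)
      vapply(split(table[[gate_center_by]], table$region),
             function(g) length(unique(g)), 1L)[names(by_region)]
    else stats::setNames(rep(1L, length(by_region)), names(by_region))
    if (all(ns - constraints > length(traits))) {
      cov_test <- covariance_structure_test(
        by_region[[1L]], by_region[[2L]], alpha = alpha,
        dof = ns - constraints)
      if (cov_test$verdict == "neither" && !override)
        stop("region covariance matrices are neither equal nor ",
             "proportional; pooled PCA refused (use override = TRUE)",
             call. = FALSE)
    }
  }
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors
  # deterministic signs: tarsus loading positive on PC1, dominant loading
  # positive elsewhere
  ti <- match("tarsus", traits)
  for (j in seq_len(ncol(L))) {
    pivot <- if (j == 1L && !is.na(ti)) ti else which.max(abs(L[, j]))
    if (L[pivot, j] < 0) L[, j] <- -L[, j]
  }
  center <- colMeans(X)
  scores <- sweep(X, 2L, center) %*% L
  dimnames(L) <- list(traits, paste0("PC", seq_along(traits)))
  colnames(scores) <- colnames(L)
  structure(list(traits = traits, center = center, loadings = L,
                 eigenvalues = pmax(e$values, 0), scores = scores,
                 cov_test = cov_test, scope = scope),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA of log traits",
      if (!is.na(x$scope)) paste0("(", x$scope, ")"), "\n")
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("  variance explained:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), pct),
            collapse = ", "), "\n")
  if (!is.null(x$cov_test)) cat("  pooling gate verdict:",
                                x$cov_test$verdict, "\n")
  invisible(x)
}

#' Project new individuals onto a fitted PCA model
#' @param model a `pca_model`.
#' @param table morphology table with the model's trait columns (mm).
#' @return score matrix, rows in input order.
#' @export
pca_scores <- function(model, table) {
  X <- log(as.matrix(table[, model$traits, drop = FALSE]))
  s <- sweep(X, 2L, model$center) %*% model$loadings
  colnames(s) <- colnames(model$loadings)
  s
}

#' Normalize PC scores within era to the [-1, 1] range
#'
#' Each score is divided by the largest absolute score *within its era*, so
#' each era spans `[-1, 1]` with at least one value at magnitude 1.
#' Because eras are normalized independently, cross-era ratios are not
#' preserved -- the normalization is a visualization aid, not a scale
#' conversion.
#'
#' @param scores numeric vector of PC scores.
#' @param era optional factor/character of the same length; `NULL` treats
#'   the whole vector as one group.
#' @return normalized numeric vector.
#' @export
normalize_scores <- function(scores, era = NULL) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  grp <- if (is.null(era)) rep_len("all", length(scores)) else as.character(era)
  out <- scores
  for (g in unique(grp)) {
    i <- grp == g
    m <- max(abs(scores[i]))
    if (m == 0) stop("all-zero scores in era ", g, call. = FALSE)
    out[i] <- scores[i] / m
  }
  out
}

#' Filter a morphology table to the pre-deforestation historical window
#'
#' Keeps rows with `collection_year` strictly before `cutoff_year` (a
#' specimen from the cutoff year itself is excluded) and drops rows whose
#' habitat could not be assigned (missing locality), reporting the counts.
#'
#' @param table morphology table.
#' @param cutoff_year exclusive upper bound (default 1935).
#' @return the filtered table; dropped-row counts attached as attribute
#'   `"dropped"` and reported via `message()`.
#' @export
filter_historical <- function(table, cutoff_year = 1935) {
  no_year <- is.na(table$collection_year)
  too_late <- !no_year & table$collection_year >= cutoff_year
  no_habitat <- is.na(table$habitat)
  keep <- !(no_year | too_late | no_habitat)
  dropped <- c(year_missing = sum(no_year),
               at_or_after_cutoff = sum(too_late & !no_year),
               habitat_missing = sum(no_habitat & !no_year & !too_late))
  message(sprintf(
    "filter_historical: kept %d of %d rows (dropped %d >= %d, %d missing year, %d missing habitat)",
    sum(keep), nrow(table), dropped[["at_or_after_cutoff"]], cutoff_year,
    dropped[["year_missing"]], dropped[["habitat_missing"]]))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Serialize a PCA model as a structured text artifact
#' @param model a `pca_model`.
#' @param path output path (JSON).
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(list(
    traits = model$traits, center = unname(model$center),
    loadings = model$loadings, eigenvalues = model$eigenvalues,
    scope = model$scope), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PCA model written by [write_pca_model()]
#' @param path JSON path.
#' @export
read_pca_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(j$loadings)
  dimnames(L) <- list(j$traits, paste0("PC", seq_along(j$traits)))
  structure(list(traits = j$traits,
                 center = stats::setNames(j$center, j$traits),
                 loadings = L, eigenvalues = j$eigenvalues,
                 scores = NULL, cov_test = NULL,
                 scope = j$scope %||% NA_character_),
            class = "pca_model")
}
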