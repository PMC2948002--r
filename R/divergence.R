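# Divergence module: Wilcoxon rank-sum tests (exact enumeration and normal
# approximation), Dunn-Sidak family-wise control, habitat and era contrasts,
# and between-habitat F_ST summaries.

# Null distribution of the Mann-Whitney U statistic for group sizes m, n
# (no ties): counts N(u) of rank assignments with U = u, u = 0..m*n, via the
# partition recurrence N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
mw_null_probs <- function(m, n) {
  len <- m * n + 1L
  unit <- c(1, rep(0, len - 1L))
  prev <- rep(list(unit), n + 1L)          # m' = 0
  for (mi in seq_len(m)) {
    cur <- vector("list", n + 1L)
    cur[[1L]] <- unit                      # n' = 0
    for (ni in seq_len(n)) {
      shifted <- c(rep(0, ni), prev[[ni + 1L]][seq_len(len - ni)])
      cur[[ni + 1L]] <- shifted + cur[[ni]]
    }
    prev <- cur
  }
  counts <- prev[[n + 1L]]
  counts / sum(counts)
}

#' Wilcoxon rank-sum test for two independent samples
#'
#' Two-sided test of location difference. The statistic `W` is the
#' Mann-Whitney U for `x` (rank sum of `x` minus its minimum). The p-value
#' is exact -- by enumeration of the null U distribution -- when the
#' smaller group has at most `exact_max` observations and the pooled data
#' are tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used. Both paths are exposed via `exact`.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   (default) chooses automatically.
#' @param exact_max automatic-exact cutoff on the smaller group size
#'   (default 10).
#' @return List: `W`, `p`, `method` (`"exact"` or `"normal"`), group sizes.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL, exact_max = 10L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  use_exact <- exact %||% (min(m, n) <= exact_max && !ties)
  if (use_exact && ties)
    stop("exact p-value is unavailable with ties", call. = FALSE)
  if (use_exact) {
    pr <- mw_null_probs(m, n)
    lo <- sum(pr[seq_len(U + 1L)])               # P(U <= u)
    hi <- sum(pr[(U + 1L):length(pr)])           # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(r)
    sigma2 <- (m * n / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- U - mu
    z <- z - sign(z) * 0.5                       # continuity correction
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = U, p = p, method = method, n = c(m, n))
}

#' Dunn-Sidak family-wise corrected significance threshold
#'
#' For `m` tests at family-wise level `alpha`, the per-test threshold is
#' `1 - (1 - alpha)^(1/m)`; for the six trait comparisons of the habitat
#' contrast this gives 0.0085 at `alpha = 0.05`.
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests in the family, `>= 1`.
#' @return the corrected per-test threshold.
#' @export
dunn_sidak <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(m) || m < 1)
    stop("`m` must be >= 1", call. = FALSE)
  1 - (1 - alpha)^(1 / m)
}

# The six analysis traits of the habitat contrast: PC1, the raw traits that
# track tree cover, and size-corrected wing and tail. PC2 and upper
# mandible are excluded (not associated with tree cover).
DIVERGENCE_TRAITS <- c("PC1", "tarsus", "wing", "tail", "wing_sc", "tail_sc")

#' Derive analysis-scale trait columns from a morphology table
#'
#' Builds the derived variables every divergence analysis runs on: log mm
#' traits, PC scores from a pooled covariance PCA (gated on covariance
#' structure when two regions are present), and size-corrected wing/tail
#' (log-log residuals on tarsus). All columns are in input row order.
#'
#' @param table morphology table.
#' @param pca optional fitted `pca_model` to score against (otherwise one
#'   is fitted to `table`).
#' @param override pass through the PCA pooling gate.
#' @param check_covariance apply the pooling gate (default TRUE; era
#'   contrasts disable it, see [era_divergence()]).
#' @return Data frame of id/meta columns plus `PC1`, `PC2`, log `tarsus`,
#'   `wing`, `tail`, `upper_mandible`, `wing_sc`, `tail_sc`. The fitted PCA
#'   is attached as attribute `"pca"` and the size-correction fits as
#'   `"size_correction"`.
#' @export
derive_traits <- function(table, pca = NULL, override = FALSE,
                          check_covariance = TRUE) {
  meta_cols <- intersect(c("individual_id", "site_id", "region", "habitat",
                           "era", "collection_year", "tree_cover"),
                         names(table))
  if (is.null(pca))
    pca <- pooled_pca(table, override = override,
                      check_covariance = check_covariance)
  sc <- pca_scores(pca, table)
  wing_fit <- size_correct(table, "wing")
  tail_fit <- size_correct(table, "tail")
  out <- cbind(table[, meta_cols, drop = FALSE],
               PC1 = sc[, "PC1"], PC2 = sc[, "PC2"],
               tarsus = log(table$tarsus), wing = log(table$wing),
               tail = log(table$tail),
               upper_mandible = log(table$upper_mandible),
               wing_sc = wing_fit$residuals, tail_sc = tail_fit$residuals)
  rownames(out) <- NULL
  attr(out, "pca") <- pca
  attr(out, "size_correction") <- list(wing = wing_fit, tail = tail_fit)
  out
}

div_row <- function(trait, region, era, x, y, labels, alpha_corr, exact) {
  w <- wilcoxon_rank_sum(x, y, exact = exact)
  data.frame(
    trait = trait, region = region, era = era,
    group_1 = labels[1L], n_1 = length(x), mean_1 = mean(x),
    se_1 = stats::sd(x) / sqrt(length(x)),
    group_2 = labels[2L], n_2 = length(y), mean_2 = mean(y),
    se_2 = stats::sd(y) / sqrt(length(y)),
    W = w$W, p_two_sided = w$p, method = w$method,
    alpha_corrected = alpha_corr,
    significant = w$p <= alpha_corr,
    stringsAsFactors = FALSE)
}

#' Rainforest-vs-ecotone divergence tests within a region
#'
#' One two-sided Wilcoxon rank-sum test per analysis trait, comparing
#' forest and ecotone individuals within `region`, with the per-test
#' threshold Dunn-Sidak-corrected for the family of `length(traits)`
#' comparisons. The input must be restricted to continental lowland
#' rainforest and ecotone sites: montane or island rows are an error, not
#' silently dropped.
#'
#' @param table morphology table (typically both regions, so that PCA and
#'   size correction are fitted on the pooled data).
#' @param region region to test within.
#' @param traits derived trait columns to test (default the six analysis
#'   traits).
#' @param alpha family-wise level (default 0.05).
#' @param exact passed to [wilcoxon_rank_sum()].
#' @param derived optionally a pre-computed [derive_traits()] frame.
#' @return A `divergence_result` data frame, one row per trait.
#' @export
habitat_divergence <- function(table, region, traits = DIVERGENCE_TRAITS,
                               alpha = 0.05, exact = NULL, derived = NULL) {
  bad <- setdiff(unique(table$habitat), c("forest", "ecotone"))
  if (length(bad))
    stop("table contains non-lowland habitats (", paste(bad, collapse = ", "),
         "); restrict to forest and ecotone sites first", call. = FALSE)
  d <- derived %||% derive_traits(table)
  d <- d[d$region == region, , drop = FALSE]
  if (!all(c("forest", "ecotone") %in% d$habitat))
    stop("both habitats must be present in region ", region, call. = FALSE)
  a_corr <- dunn_sidak(alpha, length(traits))
  out <- do.call(rbind, lapply(traits, function(tr) {
    div_row(tr, region, "contemporary",
            d[[tr]][d$habitat == "forest"], d[[tr]][d$habitat == "ecotone"],
            c("forest", "ecotone"), a_corr, exact)
  }))
  class(out) <- c("divergence_result", "data.frame")
  out
}

#' Between-region divergence within each era
#'
#' For rainforest populations only, tests West-vs-Central (i.e. region 1 vs
#' region 2) differences per trait, separately within the contemporary and
#' historical cohorts, using era-specific PCAs (scores are never compared
#' across eras without normalization). The covariance pooling gate is not
#' re-applied to the per-era PCAs: that verification belongs to the pooled
#' contemporary analysis, and museum series are far too small for the gate
#' to be meaningful. Size-corrected wing and tail are
#' omitted from the historical family when the historical log-log
#' size-correction regression is not significant at `sc_alpha`.
#'
#' @param contemp,historical morphology tables for the two eras.
#' @param traits candidate derived traits (default the six analysis traits).
#' @param alpha per-test level; uncorrected by default for this family, set
#'   `correct_family = TRUE` to Dunn-Sidak-correct it.
#' @param correct_family apply Dunn-Sidak across the per-era family.
#' @param sc_alpha threshold for the historical size-correction gate.
#' @param exact passed to [wilcoxon_rank_sum()].
#' @return A `divergence_result` data frame with an `era` column; omitted
#'   historical traits are recorded in attribute `"omitted"`.
#' @export
era_divergence <- function(contemp, historical, traits = DIVERGENCE_TRAITS,
                           alpha = 0.05, correct_family = FALSE,
                           sc_alpha = 0.05, exact = NULL) {
  eras <- list(contemporary = contemp, historical = historical)
  omitted <- character()
  rows <- list()
  for (era in names(eras)) {
    tab <- eras[[era]]
    tab <- tab[tab$habitat == "forest", , drop = FALSE]
    regs <- unique(tab$region)
    if (length(regs) < 2L)
      stop("era '", era, "' has a single region; between-region tests ",
           "are impossible", call. = FALSE)
    d <- derive_traits(tab, check_covariance = FALSE)
    tr_era <- traits
    if (era == "historical") {
      scf <- attr(d, "size_correction")
      drop_sc <- c("wing_sc", "tail_sc")[c(scf$wing$p_value > sc_alpha,
                                           scf$tail$p_value > sc_alpha)]
      if (length(drop_sc)) {
        omitted <- drop_sc
        tr_era <- setdiff(tr_era, drop_sc)
      }
    }
    a_corr <- if (correct_family) dunn_sidak(alpha, length(tr_era)) else alpha
    rows[[era]] <- do.call(rbind, lapply(tr_era, function(tr) {
      div_row(tr, paste(regs[1L], "vs", regs[2L]), era,
              d[[tr]][d$region == regs[1L]], d[[tr]][d$region == regs[2L]],
              regs[1:2], a_corr, exact)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("divergence_result", "data.frame")
  attr(out, "omitted") <- omitted
  out
}

#' Summarize pairwise F_ST between habitats
#'
#' Collects the entries of a symmetric pairwise F_ST matrix for population
#' pairs whose habitats differ and reports their mean, standard error,
#' range, and count. The diagonal and within-habitat pairs are ignored.
#'
#' @param pairwise symmetric numeric matrix with population names as
#'   dimnames; values in `[0, 1]`.
#' @param habitat_of named character vector mapping population to habitat.
#' @param region optional label.
#' @return An `fst_summary` list: `mean_fst`, `se_fst` (`NA` with
#'   `se_defined = FALSE` when only one pair), `range`, `n_pairs`, `values`.
#' @export
fst_between_habitat_summary <- function(pairwise, habitat_of,
                                        region = NA_character_) {
  m <- as.matrix(pairwise)
  if (nrow(m) != ncol(m) || max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stop("`pairwise` must be a symmetric square matrix", call. = FALSE)
  pops <- rownames(m) %||% names(habitat_of)[seq_len(nrow(m))]
  hab <- habitat_of[pops]
  if (anyNA(hab)) stop("missing habitat for some populations", call. = FALSE)
  vals <- numeric()
  for (i in seq_len(nrow(m) - 1L))
    for (j in (i + 1L):ncol(m))
      if (hab[i] != hab[j]) vals <- c(vals, m[i, j])
  if (length(vals) == 0L)
    stop("no between-habitat population pair", call. = FALSE)
  if (any(vals < 0 | vals > 1))
    stop("F_ST values must lie in [0, 1]", call. = FALSE)
  n <- length(vals)
  structure(list(region = region, mean_fst = mean(vals),
                 se_fst = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
                 se_defined = n > 1, range = range(vals), n_pairs = n,
                 values = vals),
            class = "fst_summary")
}

#' @export
print.fst_summary <- function(x, ...) {
  cat(sprintf("Between-habitat F_ST%s: mean = %.3f%s, range = %.3g-%.3g, n = %d pairs\n",
              if (is.na(x$region)) "" else paste0(" (", x$region, ")"),
              x$mean_fst,
              if (x$se_defined) sprintf(" +/- %.3f SE", x$se_fst)
              else " (SE undefined, single pair)",
              x$range[1L], x$range[2L], x$n_pairs))
  invisible(x)
}

#' Read a pairwise F_ST matrix and habitat map from CSV
#'
#' @param matrix_path square CSV, first column = population names, header =
#'   population names.
#' @param habitat_path CSV with columns `population, habitat`.
#' @return list with `pairwise` (matrix) and `habitat_of` (named vector).
#' @export
read_fst_matrix <- function(matrix_path, habitat_path) {
  m <- utils::read.csv(matrix_path, row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  h <- utils::read.csv(habitat_path, stringsAsFactors = FALSE)
  list(pairwise = m,
       habitat_of = stats::setNames(h$habitat, h$population))
}
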