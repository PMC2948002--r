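# Internal helpers: seeding, RNG hygiene, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

KM_PER_DEGREE <- 111.32

#' Derive a reproducible substream seed from a global seed and a stage name
#'
#' A single global integer seed is propagated to named substreams (e.g.
#' `"raster"`, `"sites"`, `"individuals"`) so that pipeline stages can be
#' regenerated independently without re-running earlier stages.
#'
#' @param seed integer global seed.
#' @param name character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`, a deterministic function of
#'   `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 1009)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Run code with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Multivariate normal draws via Cholesky; sigma must be symmetric PD.
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  L <- tryCatch(chol(sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  sweep(z %*% L, 2L, mu, `+`)
}

is_symmetric_pd <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m))) &&
    !inherits(tryCatch(chol(m), error = function(e) e), "error")
}

log_det <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) stop("matrix has non-positive determinant", call. = FALSE)
  as.numeric(d$modulus)
}
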