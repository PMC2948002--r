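test_that("size correction: residual geometry and parameter recovery", {
  set.seed(12)
  tarsus <- exp(rnorm(500, log(20), 0.05))
  wing <- exp(0.8 * log(tarsus) + rnorm(500, 0, 0.01))
  tab <- data.frame(tarsus = tarsus, wing = wing, tail = wing,
                    upper_mandible = tarsus)
  fit <- size_correct(tab, "wing")
  expect_abs_lt(sum(fit$residuals), 1e-9)
  expect_abs_lt(cor(fit$residuals, log(tarsus)), 1e-12)
  se <- summary(stats::lm(log(wing) ~ log(tarsus)))$coefficients[2, 2]
  expect_abs_lt(fit$slope - 0.8, 3 * se)
})

test_that("size correction refuses invalid requests", {
  tab <- data.frame(tarsus = c(20, 21, 22), wing = c(60, 61, 62),
                    upper_mandible = c(14, 14, 15))
  expect_error(size_correct(tab, "upper_mandible"), "not size-corrected")
  expect_error(size_correct(tab, "tarsus"), "not size-corrected")
  expect_error(size_correct(tab[1:2, ], "wing"), "3 individuals")
})

test_that("equality LRT holds its nominal size and rho ~ 1 under equality", {
  p <- 4; n <- 500
  sigma <- matrix(0.5, p, p) * 0.0025; diag(sigma) <- 0.0025
  rej <- logical(500); rhos <- numeric(500)
  set.seed(77)
  for (i in seq_len(500)) {
    x1 <- ecotone:::rmvnorm_chol(n, rep(0, p), sigma)
    x2 <- ecotone:::rmvnorm_chol(n, rep(0, p), sigma)
    res <- covariance_structure_test(x1, x2)
    rej[i] <- res$lrt_equality$p < 0.05
    rhos[i] <- res$proportionality_constant
  }
  # binomial 95% CI around 0.05 at 500 simulations: [0.031, 0.069]
  expect_gte(mean(rej), 0.0309)
  expect_lte(mean(rej), 0.0691)
  expect_abs_lt(mean(rhos) - 1, 0.02)
})

test_that("proportionality LRT recovers rho = 2 and accepts the model", {
  p <- 4; n <- 2000
  sigma <- matrix(0.3, p, p) * 0.01; diag(sigma) <- 0.01
  set.seed(5)
  x1 <- ecotone:::rmvnorm_chol(n, rep(0, p), sigma)
  x2 <- ecotone:::rmvnorm_chol(n, rep(0, p), 2 * sigma)
  res <- covariance_structure_test(x1, x2)
  expect_gt(res$lrt_proportionality$p, 0.05)
  se_rho <- 2 * sqrt(2 / p * (1 / n + 1 / n))     # delta-method SE
  expect_abs_lt(res$proportionality_constant - 2, 3 * se_rho)
  expect_equal(res$lrt_proportionality$dof, p * (p + 1) / 2 - 1)
  expect_equal(res$lrt_equality$dof, p * (p + 1) / 2)
})

test_that("covariance test is invariant to trait reordering and rejects
           degenerate input", {
  set.seed(9)
  sigma <- diag(4) * 0.01 + 0.002
  x1 <- ecotone:::rmvnorm_chol(100, rep(0, 4), sigma)
  x2 <- ecotone:::rmvnorm_chol(80, rep(0, 4), sigma)
  a <- covariance_structure_test(x1, x2)
  perm <- c(3, 1, 4, 2)
  b <- covariance_structure_test(x1[, perm], x2[, perm])
  expect_equal(a$lrt_equality$statistic, b$lrt_equality$statistic,
               tolerance = 1e-9)
  expect_equal(a$lrt_proportionality$statistic,
               b$lrt_proportionality$statistic, tolerance = 1e-8)
  expect_error(covariance_structure_test(x1[1:3, ], x2), "n > number")
  x_sing <- cbind(x1[, 1:3], x1[, 3])            # rank-deficient
  expect_error(covariance_structure_test(x_sing, x2), "singular|positive")
})

test_that("PCA matches an independent eigensolver and is well-normalized", {
  tab <- make_region_table("central", 60, 40, seed = 14)
  pca <- pooled_pca(tab)
  X <- log(as.matrix(tab[, c("tarsus", "wing", "tail", "upper_mandible")]))
  # oracle: SVD of the centered data matrix
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  or_load <- sv$v
  for (j in 1:4) if (sum(or_load[, j] * pca$loadings[, j]) < 0)
    or_load[, j] <- -or_load[, j]
  expect_lt(max(abs(abs(or_load) - abs(pca$loadings))), 1e-8)
  expect_equal(sum(pca$eigenvalues), sum(diag(cov(X))), tolerance = 1e-10)
  expect_equal(crossprod(pca$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_gt(pca$loadings["tarsus", "PC1"], 0)
  # score covariance is diagonal with the eigenvalues on the diagonal
  S <- cov(pca$scores)
  expect_equal(diag(S), pca$eigenvalues, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(S - diag(diag(S)))), 1e-10)
})

test_that("the covariance gate blocks pooling of unrelated regions", {
  # region covariances with different correlation structure: neither equal
  # nor proportional
  s1 <- diag(4) * 0.0025; s1[1, 2] <- s1[2, 1] <- 0.002
  s2 <- diag(4) * 0.0025; s2[3, 4] <- s2[4, 3] <- -0.002
  model <- default_trait_model()
  model_b <- trait_gen_model(model$traits, model$log_intercepts,
                             model$cover_slopes, s1,
                             scaled_region = "west",
                             region_covariance = s2)
  tab <- rbind(
    make_region_table("central", 300, 0, model = model_b, seed = 1),
    make_region_table("west", 300, 0, model = model_b, seed = 2))
  expect_error(pooled_pca(tab), "neither")
  expect_s3_class(pooled_pca(tab, override = TRUE), "pca_model")
  expect_s3_class(pooled_pca(tab, check_covariance = FALSE), "pca_model")
})

test_that("score normalization is per-era with unit maximum", {
  expect_equal(normalize_scores(c(-2, 1, 4)), c(-0.5, 0.25, 1))
  z <- c(-1, 0.25, 1)
  expect_equal(normalize_scores(z), z)           # already normalized
  s <- c(-2, 4, 1, -10)
  era <- c("a", "a", "b", "b")
  out <- normalize_scores(s, era)
  expect_equal(out, c(-0.5, 1, 0.1, -1))
  expect_true(all(tapply(abs(out), era, max) == 1))
  expect_error(normalize_scores(c(0, 0), c("a", "a")), "all-zero")
  expect_error(normalize_scores(numeric()), "empty")
})

test_that("historical filter applies the strict 1935 cutoff", {
  tab <- data.frame(collection_year = c(1934, 1935, 1936, NA, 1920),
                    habitat = c("forest", "forest", "forest", "forest", NA))
  out <- suppressMessages(filter_historical(tab))
  expect_equal(out$collection_year, 1934)        # 1935 itself excluded
  expect_equal(unname(attr(out, "dropped")["at_or_after_cutoff"]), 2)
  expect_equal(unname(attr(out, "dropped")["habitat_missing"]), 1)
  expect_message(filter_historical(tab), "kept 1 of 5")
})

test_that("PCA models serialize and score new data identically", {
  tab <- make_region_table("central", 30, 20, seed = 3)
  pca <- pooled_pca(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(pca, path)
  pca2 <- read_pca_model(path)
  expect_equal(pca_scores(pca2, tab), pca$scores, tolerance = 1e-12)
})
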