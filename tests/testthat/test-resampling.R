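ref_table <- function(n_f = 60, n_e = 30, seed = 2,
                      model = default_trait_model())
  make_region_table("central", n_f, n_e, model = model, seed = seed)

test_that("stratified bootstrap null: degenerate and identity cases", {
  src <- ref_table()
  src$wing <- 63                                   # constant trait
  null <- stratified_bootstrap_null(src, 10, 5, "wing", B = 50, seed = 1)
  expect_true(all(null == 0))

  src2 <- ref_table()
  nf <- sum(src2$habitat == "forest"); ne <- sum(src2$habitat == "ecotone")
  null_id <- stratified_bootstrap_null(src2, nf, ne, "wing", B = 1,
                                       seed = 1, identity_resample = TRUE)
  lw <- log(src2$wing)
  obs <- abs(mean(lw[src2$habitat == "forest"]) -
               mean(lw[src2$habitat == "ecotone"]))
  expect_equal(as.numeric(null_id), obs)
})

test_that("null distribution mean matches the analytic divergence", {
  # forest ~ N(10, 1), ecotone ~ N(12, 1): |divergence| concentrates at 2
  set.seed(3)
  src <- data.frame(
    habitat = rep(c("forest", "ecotone"), c(2000, 2000)),
    site_id = "s1")
  vals <- c(rnorm(2000, 10), rnorm(2000, 12))
  null <- stratified_bootstrap_null(src, 400, 400, "x", B = 2000,
                                    seed = 4, values = vals)
  # the dominant error is the source-sample estimate of the true mean
  # difference: SE = sqrt(1/2000 + 1/2000)
  expect_abs_lt(mean(null) - 2, 3 * sqrt(2 / 2000))
})

test_that("bootstrap machinery is deterministic and validates input", {
  src <- ref_table()
  n1 <- stratified_bootstrap_null(src, 27, 11, "PC1", B = 200, seed = 9)
  n2 <- stratified_bootstrap_null(src, 27, 11, "PC1", B = 200, seed = 9)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_false(identical(
    as.numeric(n1),
    as.numeric(stratified_bootstrap_null(src, 27, 11, "PC1", B = 200,
                                         seed = 10))))
  expect_error(stratified_bootstrap_null(src, 0, 5, "wing"), ">= 1")
  expect_error(stratified_bootstrap_null(
    src[src$habitat == "forest", ], 5, 5, "wing"), "both")
  expect_error(stratified_bootstrap_null(src, 5, 5, "wing", B = 0), ">= 1")
})

test_that("bootstrap p: definition, reporting convention, monotonicity", {
  null <- c(1, 2, 3, 4)
  expect_equal(bootstrap_p(null, 2)$p, 0.5)
  expect_equal(bootstrap_p(null, 10)$p, 1)         # observed >= max
  low <- bootstrap_p(null, 0.5)
  expect_equal(low$p, 0)
  expect_equal(low$report, "p < 0.25")
  b1000 <- bootstrap_p(runif(1000, 1, 2), 0.5)
  expect_equal(b1000$report, "p < 0.001")
  obs_grid <- seq(0, 5, by = 0.25)
  ps <- vapply(obs_grid, function(o) bootstrap_p(null, o)$p, numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_error(bootstrap_p(numeric(), 1), "empty")
})

test_that("population-level bootstrap: degenerate single sites and
           determinism", {
  src <- make_region_table("central", 40, 20, n_forest_sites = 1,
                           n_ecotone_sites = 1, seed = 12)
  null <- population_bootstrap_null(src, c(forest = 1, ecotone = 1),
                                    "wing", B = 25, seed = 3)
  lw <- log(src$wing)
  obs <- abs(mean(lw[src$habitat == "forest"]) -
               mean(lw[src$habitat == "ecotone"]))
  expect_true(all(abs(null - obs) < 1e-12))
  src6 <- make_region_table("central", 60, 30, n_forest_sites = 6,
                            n_ecotone_sites = 3, seed = 13)
  a <- population_bootstrap_null(src6, c(forest = 4, ecotone = 3), "PC1",
                                 B = 100, seed = 7)
  b <- population_bootstrap_null(src6, c(forest = 4, ecotone = 3), "PC1",
                                 B = 100, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(population_bootstrap_null(src6, c(forest = 4), "PC1"),
               "ecotone")
})

test_that("population-level null is wider under site heterogeneity", {
  # inject strong site effects: site-level means differ, so resampling
  # whole sites propagates more variance than resampling individuals
  wider <- logical(50)
  for (i in seq_len(50)) {
    set.seed(8000 + i)
    sites <- rep(sprintf("s%02d", 1:10), each = 12)
    hab <- rep(c("forest", "ecotone"), c(72, 48))
    site_eff <- rep(rnorm(10, 0, 0.6), each = 12)
    vals <- ifelse(hab == "forest", 10, 11) + site_eff + rnorm(120, 0, 0.3)
    src <- data.frame(site_id = sites, habitat = hab)
    ni <- stratified_bootstrap_null(src, 24, 12, "x", B = 400,
                                    seed = i, values = vals)
    np <- population_bootstrap_null(src, c(forest = 3, ecotone = 2), "x",
                                    B = 400, seed = i, values = vals)
    wider[i] <- var(as.numeric(np)) > var(as.numeric(ni))
  }
  expect_gte(mean(wider), 0.95)
})

test_that("individual and population levels coincide for singleton sites", {
  # one individual per site, site counts = individual counts, same seed:
  # the two levels must produce the identical null distribution
  src <- ref_table(12, 8, seed = 31)
  src$site_id <- sprintf("s%02d", seq_len(nrow(src)))  # singleton sites
  src <- src[order(src$site_id), ]
  ni <- stratified_bootstrap_null(src, 7, 4, "wing", B = 300, seed = 5)
  np <- population_bootstrap_null(src, c(forest = 7, ecotone = 4), "wing",
                                  B = 300, seed = 5)
  expect_equal(as.numeric(ni), as.numeric(np), tolerance = 1e-12)
})

test_that("full bootstrap divergence test wraps the pieces coherently", {
  src <- ref_table(80, 40, seed = 17)
  focal <- make_region_table("west", 27, 11, model = flat_model(),
                             cover_forest = 50, cover_ecotone = 45,
                             seed = 18)
  res <- bootstrap_divergence_test(src, focal, "wing", B = 500, seed = 2)
  expect_s3_class(res, "bootstrap_result")
  expect_length(res$null_distribution, 500)
  expect_equal(res$p,
               mean(res$null_distribution <= res$observed_abs_divergence))
  # homogenized focal region vs strongly divergent reference: small p
  expect_lt(res$p, 0.2)
})

test_that("calibration harness exposes B = 1 degeneracy and power", {
  model <- default_trait_model()
  cal1 <- calibrate_null(model, B = 1, n_sims = 30, seed = 6)
  expect_true(all(cal1$p_values %in% c(0, 1)))
  # focal region with zero divergence, reference strongly divergent:
  # the test should reject nearly always
  cal_pow <- calibrate_null(model, focal_model = flat_model(),
                            B = 300, n_sims = 60, seed = 7)
  expect_gte(cal_pow$rejection_rate, 0.95)
})
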