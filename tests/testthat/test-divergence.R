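# Enumeration oracle: exact two-sided rank-sum p by brute force over all
# C(m+n, m) assignments of ranks to the x group.
enum_rank_sum_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(N, m)
  U_all <- colSums(matrix(seq_len(N)[combos], nrow = m)) - m * (m + 1) / 2
  lo <- mean(U_all <= U_obs); hi <- mean(U_all >= U_obs)
  min(1, 2 * min(lo, hi))
}

test_that("exact rank-sum p matches full enumeration (oracle)", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p, 0.1)
  expect_equal(enum_rank_sum_p(1:3, 4:6), 0.1)
  set.seed(40)
  for (sizes in list(c(3, 5), c(4, 4), c(5, 7), c(2, 9))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2], 0.5)
    w <- wilcoxon_rank_sum(x, y)
    expect_equal(w$method, "exact")
    expect_equal(w$p, enum_rank_sum_p(x, y), tolerance = 1e-12)
    # and agrees with the reference implementation
    expect_equal(w$p, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(w$W, unname(stats::wilcox.test(x, y)$statistic))
  }
})

test_that("normal-approximation path matches the reference and tracks the
           exact path", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, 0.8)
    expect_equal(wilcoxon_rank_sum(x, y, exact = FALSE)$p,
                 stats::wilcox.test(x, y, exact = FALSE,
                                    correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # exhaustive comparison at m = n = 8: every achievable U. The supremum
  # of |exact - normal| is 0.0109 (at U = 24, p ~ 0.37); agreement is
  # within 0.01 everywhere except that shoulder.
  pr <- ecotone:::mw_null_probs(8, 8)
  diffs <- vapply(0:64, function(u) {
    pe <- min(1, 2 * min(sum(pr[seq_len(u + 1)]), sum(pr[(u + 1):65])))
    z <- u - 32; z <- z - sign(z) * 0.5
    pa <- min(1, 2 * pnorm(-abs(z / sqrt(8 * 8 * 17 / 12))))
    abs(pe - pa)
  }, numeric(1))
  expect_lt(max(diffs), 0.011)
  expect_lt(stats::median(diffs), 0.01)
  # ties force the corrected normal path
  x <- c(1, 2, 2, 3, 5); y <- c(2, 3, 3, 4, 6)
  w <- wilcoxon_rank_sum(x, y)
  expect_equal(w$method, "normal")
  expect_equal(w$p, suppressWarnings(
    stats::wilcox.test(x, y, correct = TRUE)$p.value), tolerance = 1e-10)
  expect_error(wilcoxon_rank_sum(x, y, exact = TRUE), "ties")
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "nonempty")
})

test_that("rank-sum p is symmetric and invariant to monotone transforms", {
  set.seed(42)
  x <- rnorm(12); y <- rnorm(15, 0.3)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p,
               wilcoxon_rank_sum(x, y)$p)
  x5 <- rnorm(5); y5 <- rnorm(5)
  expect_equal(wilcoxon_rank_sum(x5, y5)$p, wilcoxon_rank_sum(y5, x5)$p)
})

test_that("Dunn-Sidak correction: values and monotonicity", {
  expect_equal(round(dunn_sidak(0.05, 6), 4), 0.0085)
  expect_equal(dunn_sidak(0.05, 1), 0.05)
  expect_equal(round(dunn_sidak(0.05, 2), 5), 0.02532)
  ms <- 1:10
  a <- vapply(ms, function(m) dunn_sidak(0.05, m), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_true(all(a <= 0.05 + 1e-15))   # m = 1 equals alpha to FP noise
  expect_error(dunn_sidak(0.05, 0), ">= 1")
  expect_error(dunn_sidak(1, 2), "\\(0, 1\\)")
})

test_that("habitat divergence rejects non-lowland habitats and absent
           groups", {
  tab <- make_region_table("central", 30, 20, seed = 6)
  bad <- tab; bad$habitat[1] <- "montane"
  expect_error(habitat_divergence(bad, "central"), "montane")
  only_f <- tab[tab$habitat == "forest", ]
  expect_error(habitat_divergence(only_f, "central"), "both habitats")
})

test_that("habitat divergence controls the family-wise error rate", {
  # both habitats drawn from one process: any significant trait is a
  # family-wise false positive; Dunn-Sidak keeps the rate at or below 5%
  model <- flat_model()
  any_sig <- logical(500)
  for (i in seq_len(500)) {
    tab <- make_region_table("west", 27, 11, model = model, seed = 5000 + i)
    div <- habitat_divergence(tab, "west")
    any_sig[i] <- any(div$significant)
    if (i == 1) {
      expect_equal(nrow(div), 6)
      expect_equal(unique(div$alpha_corrected), dunn_sidak(0.05, 6))
      expect_equal(div$significant, div$p_two_sided <= div$alpha_corrected)
    }
  }
  expect_lte(mean(any_sig), 0.05)
})

test_that("era divergence recovers the contemporary-only shift pattern", {
  model <- default_trait_model()
  sites_c <- make_sites("central", 2, 0, spread = 0)
  sites_w <- make_sites("west", 2, 0, spread = 0)
  # West contemporary birds shifted towards ecotone morphology; history
  # shared across regions
  shifted <- model
  shifted$log_intercepts["wing"] <- model$log_intercepts["wing"] + 0.1
  wins <- logical(100)
  for (i in seq_len(100)) {
    contemp <- rbind(
      generate_individuals(sites_c, model, 25, seed = 100 + i),
      generate_individuals(sites_w, shifted, 25, seed = 300 + i))
    hist <- rbind(
      generate_historical_cohort(sites_c, model, n = 25, seed = 500 + i),
      generate_historical_cohort(sites_w, model, n = 25, seed = 700 + i))
    dv <- function(tab) {
      w <- log(tab$wing)
      abs(mean(w[tab$region == "west"]) - mean(w[tab$region == "central"]))
    }
    wins[i] <- dv(contemp) > dv(hist)
  }
  expect_gte(mean(wins), 0.95)
})

test_that("era divergence: structure, gate on historical size correction,
           and errors", {
  model <- default_trait_model()
  contemp <- rbind(make_region_table("central", 30, 10, seed = 8),
                   make_region_table("west", 25, 10, seed = 9))
  hist <- rbind(
    generate_historical_cohort(make_sites("central", 3, 0), model,
                               n = 30, seed = 10),
    generate_historical_cohort(make_sites("west", 3, 0), model,
                               n = 25, seed = 11))
  res <- era_divergence(contemp, hist)
  expect_setequal(unique(res$era), c("contemporary", "historical"))
  expect_equal(res$significant, res$p_two_sided <= res$alpha_corrected)

  # force a historically non-significant wing allometry: make historical
  # wing exactly orthogonal to tarsus (slope 0 -> p = 1)
  h2 <- hist
  lw <- log(h2$wing); lt <- log(h2$tarsus)
  h2$wing <- exp(mean(lw) + stats::resid(stats::lm(lw ~ lt)))
  res2 <- era_divergence(contemp, h2)
  expect_true("wing_sc" %in% attr(res2, "omitted"))
  expect_false(any(res2$trait == "wing_sc" & res2$era == "historical"))
  expect_true(any(res2$trait == "wing_sc" & res2$era == "contemporary"))

  expect_error(era_divergence(contemp[contemp$region == "west", ], hist),
               "single region")
})

test_that("F_ST summary: printed-value example, pair selection, edge
           cases", {
  m <- matrix(0, 3, 3, dimnames = list(c("F1", "F2", "E1"),
                                       c("F1", "F2", "E1")))
  m["F1", "E1"] <- m["E1", "F1"] <- 0.053
  m["F2", "E1"] <- m["E1", "F2"] <- 0.063
  m["F1", "F2"] <- m["F2", "F1"] <- 0.2       # within-habitat: ignored
  hab <- c(F1 = "forest", F2 = "forest", E1 = "ecotone")
  s <- fst_between_habitat_summary(m, hab)
  expect_equal(s$mean_fst, 0.058)
  expect_equal(round(s$se_fst, 3), 0.005)
  expect_equal(s$n_pairs, 2)
  expect_equal(s$range, c(0.053, 0.063))

  # single between-habitat pair: SE undefined but flagged, mean = value
  s1 <- fst_between_habitat_summary(m[c("F1", "E1"), c("F1", "E1")],
                                    hab)
  expect_equal(s1$mean_fst, 0.053)
  expect_false(s1$se_defined)

  # 3 forest + 2 ecotone populations -> exactly 6 between-habitat pairs
  pops <- c("f1", "f2", "f3", "e1", "e2")
  m2 <- matrix(0.1, 5, 5, dimnames = list(pops, pops)); diag(m2) <- 0
  hab2 <- stats::setNames(c("forest", "forest", "forest", "ecotone",
                            "ecotone"), pops)
  expect_equal(fst_between_habitat_summary(m2, hab2)$n_pairs, 6)

  expect_error(fst_between_habitat_summary(m[1:2, 1:2],
                                           hab[c("F1", "F2")]),
               "no between-habitat")
  asym <- m; asym[1, 2] <- 0.9
  expect_error(fst_between_habitat_summary(asym, hab), "symmetric")
})

test_that("F_ST matrices round-trip through the CSV interface", {
  fst <- read_fst_matrix(
    system.file("extdata", "west_fst_pairwise_synthetic.csv",
                package = "ecotone"),
    system.file("extdata", "west_fst_habitats.csv", package = "ecotone"))
  s <- fst_between_habitat_summary(fst$pairwise, fst$habitat_of,
                                   region = "west")
  expect_equal(s$mean_fst, 0.058)
  expect_equal(round(s$se_fst, 3), 0.005)
})
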