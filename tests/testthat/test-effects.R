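test_that("relative change follows |orig - agg| / orig", {
  expect_equal(relative_change(10, 9), 0.1)
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(2, 3), 0.5)
  expect_error(relative_change(0, 1), "zero")
})

test_that("effect summaries are plain arithmetic means per replicate", {
  s <- summarize_effects(c(0.05, 0.15), c(0.1, 0.3))
  expect_equal(s$mean_rcm, 0.1)
  expect_equal(s$mean_rcv, 0.2)
  set.seed(1)
  a <- runif(30); b <- runif(30)
  s2 <- summarize_effects(a, b)
  expect_equal(s2$mean_rcv, sum(b) / 30, tolerance = 1e-12)
  expect_error(summarize_effects(numeric(), numeric()), "replicate")
})

test_that("the Levene test matches car's mean-centred implementation", {
  skip_if_not_installed("car")
  set.seed(21)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    ours <- levene_test(a, b)
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(length(a), length(b)))),
                           center = mean)
    expect_equal(unname(ours$statistic), ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("the Levene test is an ANOVA on absolute deviations", {
  a <- c(1, 2, 3, 4); b <- c(1, 3, 5, 7)
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  ref <- stats::oneway.test(z ~ g,
                            data = data.frame(z = c(za, zb),
                                              g = factor(rep(1:2, each = 4))),
                            var.equal = TRUE)
  ours <- levene_test(a, b)
  expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Levene detects large scale differences and degenerates to p = 1", {
  set.seed(5)
  a <- rnorm(30)
  expect_lt(levene_test(a, 10 * a)$p.value, 0.05)
  expect_equal(levene_test(a, a)$statistic, c(W = 0))
  expect_equal(levene_test(a, a)$p.value, 1)
  expect_equal(levene_test(c(1, 1, 1), c(2, 2))$p.value, 1)
})

test_that("the Welch test matches stats::t.test on random samples", {
  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ours <- welch_ttest(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    pooled <- welch_ttest(a, b, var_equal = TRUE)
    refp <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(pooled$p.value, refp$p.value, tolerance = 1e-10)
  }
})

test_that("the Welch test separates means and degenerates sensibly", {
  set.seed(6)
  expect_lt(welch_ttest(rnorm(50), rnorm(50, mean = 5))$p.value, 1e-6)
  a <- rnorm(10)
  expect_equal(welch_ttest(a, a)$statistic, c(t = 0))
  expect_equal(welch_ttest(a, a)$p.value, 1)
  expect_equal(welch_ttest(c(2, 2), c(2, 2, 2))$p.value, 1)
})

test_that("a scaled effect grid reproduces the known MAUP trends", {
  cfg <- experiment_config(n_values = 100,
                           k_sets = list(`100` = c(12, 25, 40, 53, 67, 80, 90)),
                           instances = 10, seed = 77)
  eff <- effect_experiment(cfg)
  expect_equal(nrow(eff), 10 * 9 * 7)
  expect_true(all(eff$mean_rcm >= 0) && all(eff$mean_rcv >= 0))

  med <- dplyr::summarise(dplyr::group_by(eff, rho, k),
                          m = median(mean_rcv), .groups = "drop")
  # variance distortion decreases with spatial autocorrelation at fixed k
  by_k <- dplyr::group_by(med, k)
  cors <- dplyr::summarise(by_k, s = cor(rho, m, method = "spearman"))
  expect_true(all(cors$s <= -0.8))
  # and decreases with the number of regions at fixed rho
  by_r <- dplyr::summarise(dplyr::group_by(med, rho),
                           s = cor(k, m, method = "spearman"))
  expect_true(all(by_r$s <= -0.8))
  # the mean is essentially untouched at moderate-or-finer aggregation:
  # measured in units of the variable's spread (the raw relative change has
  # a near-zero random denominator under a mean-zero generator)
  shift <- eff$mean_rcm * abs(eff$mu_o) / sqrt(eff$sigma2_o)
  expect_lt(median(shift[eff$k >= 10]), 0.05)
  # Levene rejections fade as rho or k grows
  lev <- dplyr::summarise(dplyr::group_by(eff, rho, k),
                          rej = mean(levene_rejections / r), .groups = "drop")
  expect_lt(cor(lev$rho, lev$rej, method = "spearman"), 0)
  expect_lt(cor(lev$k, lev$rej, method = "spearman"), 0)
})
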