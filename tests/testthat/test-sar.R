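test_that("a SAR draw at rho = 0 is exactly the seeded noise vector", {
  w <- rook_lattice(6, 6)
  y <- simulate_sar(w, 0, seed = 42)
  set.seed(42)
  expect_identical(y$value, rnorm(36))
})

test_that("SAR draws are deterministic in the seed and reject unstable rho", {
  w <- rook_lattice(8, 8)
  expect_identical(simulate_sar(w, 0.7, seed = 5), simulate_sar(w, 0.7, seed = 5))
  expect_false(identical(simulate_sar(w, 0.7, seed = 5)$value,
                         simulate_sar(w, 0.7, seed = 6)$value))
  expect_error(simulate_sar(w, 1), "stable")
  expect_error(simulate_sar(w, -1.2), "stable")
})

test_that("SAR draws are mean-zero elementwise over many seeds", {
  w <- rook_lattice(10, 10)
  acc <- numeric(100)
  for (s in 1:1000) acc <- acc + simulate_sar(w, 0.5, seed = s)$value
  expect_lt(max(abs(acc / 1000)), 0.15)
})

test_that("Moran's I matches hand computations and rejects constants", {
  w <- rook_lattice(2, 2)
  expect_equal(moran_i(c(1, -1, -1, 1), w), -1, tolerance = 1e-12)
  expect_error(moran_i(rep(3, 4), w), "constant")
})

test_that("Moran's I of i.i.d. noise averages to -1/(n-1)", {
  w <- rook_lattice(30, 30)
  vals <- vapply(1:200, function(s) moran_i(simulate_sar(w, 0, seed = s), w),
                 numeric(1))
  expect_equal(mean(vals), -1 / 899, tolerance = 0.005)
})

test_that("sample Moran's I increases with the SAR parameter", {
  w <- rook_lattice(30, 30)
  rhos <- seq(-0.9, 0.9, by = 0.2)
  d <- expand.grid(rho = rhos, s = 1:30)
  d$I <- mapply(function(r, s) moran_i(simulate_sar(w, r, seed = 7000 + s), w),
                d$rho, d$s)
  expect_gt(cor(d$rho, d$I, method = "spearman"), 0.9)
  # strong positive autocorrelation is visible in almost every draw
  hi <- d$I[d$rho == 0.9]
  expect_gte(mean(hi > 0.4), 0.95)
})

test_that("ML rho estimates agree with a fine grid search of the likelihood", {
  w <- rook_lattice(7, 7)
  Wd <- oracle_dense_w(w)
  cases <- expand.grid(rho = c(-0.8, -0.4, 0, 0.4, 0.8), s = 1:10)
  for (i in seq_len(nrow(cases))) {
    yv <- simulate_sar(w, cases$rho[i], seed = 300 + i)$value
    est <- estimate_rho_ml(yv, w)
    orc <- oracle_rho_grid(yv, Wd, step = 1e-3)
    expect_lte(abs(est$rho_hat - orc$rho), 1e-3)
    # oracle dominance: the ML optimum is at least as good as every grid point
    expect_gte(est$log_likelihood + 1e-8, orc$loglik)
  }
})

test_that("rho estimation is calibrated on i.i.d. and strongly correlated data", {
  w <- rook_lattice(30, 30)
  iid <- vapply(1:100, function(s) {
    estimate_rho_ml(simulate_sar(w, 0, seed = 4000 + s), w)$rho_hat
  }, numeric(1))
  expect_gte(mean(abs(iid) < 0.1), 0.90)
  hot <- vapply(1:100, function(s) {
    estimate_rho_ml(simulate_sar(w, 0.9, seed = 5000 + s), w)$rho_hat
  }, numeric(1))
  expect_gte(mean(hot > 0.8 & hot < 0.97), 0.90)
})

test_that("rho estimation rejects degenerate inputs", {
  w <- rook_lattice(5, 5)
  expect_error(estimate_rho_ml(rep(1, 25), w), "constant")
  expect_error(estimate_rho_ml(rnorm(4), rook_lattice(2, 2)), "at least 10")
})

test_that("rank matching places values by the pattern's ranks", {
  expect_equal(rank_match(c(5, 1, 9), c(0.2, 0.9, 0.5)), c(1, 9, 5))
  # ties in the pattern break by position
  expect_equal(rank_match(c(3, 1, 2), c(0.5, 0.5, 0.1)), c(2, 3, 1))
  expect_error(rank_match(1:3, 1:4), "length")
})

test_that("rho retargeting permutes the multiset and hits the tolerance", {
  w <- rook_lattice(10, 10)
  y <- simulate_sar(w, 0.9, seed = 1)
  for (target in c(-0.9, -0.3, 0, 0.5)) {
    yr <- retarget_rho(y, w, target, seed = 50 + round(10 * target))
    expect_identical(sort(yr$value), sort(y$value))
    expect_lte(abs(attr(yr, "rho_hat") - target), 0.1)
    expect_equal(mean(yr$value), mean(y$value), tolerance = 1e-12)
    expect_equal(var(yr$value), var(y$value), tolerance = 1e-12)
  }
})

test_that("retargeting reports failure with the best deviation achieved", {
  w <- rook_lattice(10, 10)
  y <- simulate_sar(w, 0.9, seed = 2)
  expect_error(retarget_rho(y, w, -0.9, tol = 1e-6, max_attempts = 3, seed = 1),
               "failed after 3 attempts")
})
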