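test_that("component functions hit their closed-form anchor points", {
  c0 <- smaup_components(1e-12)
  expect_equal(c0$L, 1 / (1 + exp(-2.188)), tolerance = 1e-9)
  expect_equal(c0$eta, 0, tolerance = 1e-9)
  expect_equal(c0$tau, 5.319, tolerance = 1e-9)
  c1 <- smaup_components(1)
  expect_equal(c1$eta, 0.516)       # eta(1) = p
  expect_equal(c1$tau, 5.319 - 5.532)
  expect_equal(c1$L, 0.00782, tolerance = 1e-3)
  expect_error(smaup_components(0), "theta")
  expect_error(smaup_components(1.2), "theta")
})

test_that("the statistic reproduces frozen spot values to 5 decimal places", {
  expect_equal(round(smaup_statistic(0, 0.4), 5), 0.30102)
  expect_equal(round(smaup_statistic(0.9, 0.9), 5), 0.00972)
  expect_equal(round(smaup_statistic(-0.9, 0.1), 5), 0.81501)
  expect_error(smaup_statistic(1, 0.5), "rho")
})

test_that("the statistic agrees with an independent evaluation on a dense grid", {
  rho <- seq(-0.99, 0.99, length.out = 100)
  theta <- seq(0.01, 1, length.out = 100)
  g <- expand.grid(rho = rho, theta = theta)
  ours <- smaup_statistic(g$rho, g$theta)
  ref <- oracle_statistic(g$rho, g$theta)
  expect_lt(max(abs(ours - ref) / ref), 1e-12)
  expect_true(all(ours > 0 & ours < 1))
})

test_that("the statistic is monotone in theta and changes rho-direction at -beta0/beta1", {
  theta <- seq(0.01, 1, by = 0.01)
  for (rho in c(-0.9, -0.7, -0.5, -0.3, 0, 0.3, 0.5, 0.7, 0.9)) {
    m <- smaup_statistic(rho, theta)
    expect_true(all(diff(m) < 0))
  }
  rho <- seq(-0.99, 0.99, by = 0.01)
  flip <- 5.319 / 5.532              # tau changes sign here (~0.9615)
  for (th in c(0.05, 0.3, 0.6, 0.9, 0.95)) {
    expect_true(all(diff(smaup_statistic(rho, th)) < 0))
  }
  for (th in c(0.97, 0.99, 1)) {
    expect_true(all(diff(smaup_statistic(rho, th)) >= 0))
  }
  expect_lt(0.9615 - flip, 1e-4)
})

test_that("critical values look up exactly on the grid", {
  expect_equal(as.numeric(critical_value(-0.9, 25, 0.01)), 0.83702)
  expect_equal(as.numeric(critical_value(0.9, 900, 0.1)), 0.22411)
  expect_equal(as.numeric(critical_value(0, 625, 0.05)), 0.06066)
  expect_equal(attr(critical_value(0, 625, 0.05), "policy"), "exact")
  expect_error(critical_value(0, 100, 0.025), "alpha")
})

test_that("off-grid critical values follow the documented policy", {
  # rho interpolation between the 0 and 0.3 rows at N = 400
  cv <- critical_value(0.15, 400, 0.05)
  expect_equal(as.numeric(cv), (0.06961 + 0.09766) / 2, tolerance = 1e-9)
  expect_match(attr(cv, "policy"), "interpolated")
  # conservative mode takes the larger bracketing cell
  cvc <- critical_value(0.15, 400, 0.05, method = "conservative")
  expect_equal(as.numeric(cvc), 0.09766)
  # nearest N with ties toward the smaller grid size
  expect_equal(as.numeric(critical_value(0, 162.5, 0.05)),
               as.numeric(critical_value(0, 100, 0.05)))
  expect_equal(as.numeric(critical_value(0, 163, 0.05)),
               as.numeric(critical_value(0, 225, 0.05)))
  # rho beyond the grid clamps to the boundary row
  expect_equal(as.numeric(critical_value(0.95, 900, 0.05)),
               as.numeric(critical_value(0.9, 900, 0.05)))
})

test_that("pseudo-p counts strict exceedances", {
  expect_equal(pseudo_p(0.9, c(0.1, 0.2, 0.3, 0.4)), 0)
  expect_equal(pseudo_p(0.05, c(0.1, 0.2, 0.3, 0.4)), 1)
  expect_equal(pseudo_p(0.25, c(0.1, 0.2, 0.3, 0.4)), 0.5)
  expect_equal(pseudo_p(0.2, c(0.1, 0.2, 0.3, 0.4)), 0.5) # ties are not exceedances
  expect_error(pseudo_p(0.5, numeric()), "empty")
})

test_that("the packaged critical table is complete and validation names holes", {
  tab <- load_critical_table()
  expect_equal(nrow(tab), 162)
  expect_equal(tab$value[tab$rho == 0 & tab$alpha == 0.05 & tab$N == 625],
               0.06066)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[-5, ], path, row.names = FALSE)
  expect_error(load_critical_table(path), "missing cell")
})
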