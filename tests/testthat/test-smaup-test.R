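test_that("an uncorrelated variable aggregated to theta = 0.4 is flagged", {
  w <- rook_lattice(32, 32)
  y <- simulate_sar(w, 0, seed = 71)
  res <- smaup_test(y, w, k = 410)   # theta ~ 0.4, N ~ 1000
  expect_lt(abs(res$rho_hat), 0.1)
  expect_true(res$reject)
})

test_that("a strongly autocorrelated variable survives mild aggregation", {
  w <- rook_lattice(10, 15)
  y <- simulate_sar(w, 0.85, seed = 72)
  res <- smaup_test(y, w, k = 90)    # N = 150, theta = 0.6
  expect_gt(res$rho_hat, 0.6)
  expect_false(res$reject)
})

test_that("aggregation into N-1 regions never rejects", {
  for (spec in list(c(5, 5, 0.6), c(10, 10, 0), c(15, 15, -0.6))) {
    w <- rook_lattice(spec[1], spec[2])
    y <- simulate_sar(w, spec[3], seed = 73)
    res <- smaup_test(y, w, k = n_areas(w) - 1L)
    expect_lt(res$statistic, 0.008)
    expect_false(res$reject)
  }
})

test_that("the test validates k and reports pseudo-p with a null", {
  w <- rook_lattice(5, 5)
  y <- simulate_sar(w, 0.5, seed = 74)
  expect_error(smaup_test(y, w, k = 25), "smaller than the number of areas")
  nd <- generate_null(w, rho = 0.5, n_instances = 60, seed = 75)
  res <- smaup_test(y, w, k = 20, null = nd)
  expect_true(res$pseudo_p >= 0 && res$pseudo_p <= 1)
  expect_equal(res$pseudo_p, pseudo_p(res$statistic, nd))
  td <- tidy(res)
  expect_equal(td$statistic, res$statistic)
  expect_equal(td$reject, res$reject)
})

test_that("the k-scan equals a brute-force scan and flips once", {
  w <- rook_lattice(12, 12)
  y <- simulate_sar(w, 0.3, seed = 76)
  grid <- seq(15, 143, by = 2)
  sc <- k_scan(y, w, k_grid = grid)
  # brute force over the same grid with the same applied test
  dec <- vapply(grid, function(k) smaup_test(y, w, k)$reject, logical(1))
  expect_equal(sc$k_safe, min(grid[!dec]))
  expect_lte(sum(diff(dec) != 0), 1)   # single flip along the grid
  expect_equal(nrow(sc$table), length(grid))
})

test_that("a highly autocorrelated variable is safe at the smallest grid k", {
  w <- rook_lattice(12, 12)
  y <- simulate_sar(w, 0.9, seed = 77)
  grid <- seq(120, 143, by = 1)       # near N: tiny statistic everywhere
  sc <- k_scan(y, w, k_grid = grid)
  expect_equal(sc$k_safe, 120L)
  expect_true(all(!sc$table$reject))
})

test_that("multi-variable scans take the maximum of per-variable minima", {
  w <- rook_lattice(12, 12)
  y1 <- simulate_sar(w, 0.9, seed = 78)  # tolerant of aggregation
  y2 <- simulate_sar(w, 0, seed = 79)    # fragile under aggregation
  grid <- seq(15, 143, by = 2)
  s1 <- k_scan(y1, w, k_grid = grid)
  s2 <- k_scan(y2, w, k_grid = grid)
  both <- k_scan(list(a = y1, b = y2), w, k_grid = grid)
  expect_equal(both$k_safe, max(s1$k_safe, s2$k_safe))
  expect_equal(sort(unique(both$table$variable)), c("a", "b"))
})

test_that("a scan with no safe k aborts with the scan table attached", {
  w <- rook_lattice(10, 10)
  y <- simulate_sar(w, 0, seed = 80)
  err <- tryCatch(k_scan(y, w, k_grid = c(12, 15, 20)),
                  smaup_no_safe_k = function(e) e)
  expect_s3_class(err, "smaup_no_safe_k")
  expect_s3_class(err$scan_table, "data.frame")
  expect_true(all(err$scan_table$reject))
})
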