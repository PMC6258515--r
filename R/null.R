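# Shared rejection-sampling engine for the null distribution and the power
# and size experiments. Each attempt draws a SAR variable, a region count k
# uniform on {floor(0.1N)+1, ..., N-1}, and r random contiguous
# aggregations; the instance is retained when every aggregation's Levene
# test agrees with the required regime: all r non-rejections under H0
# ("null"), all r rejections under H1 ("alt"). The loop exits an attempt at
# the first disagreeing aggregation. For retained instances the statistic is
# evaluated at theta = k/N with the generator's rho label (default; the
# quantity the critical-value table is indexed by) or the ML estimate.
sample_instances <- function(w, rho, n_instances, mode = c("null", "alt"),
                             r = 30, alpha_levene = 0.05, seed = NULL,
                             rho_input = c("label", "estimate"),
                             max_attempts = 1000 * n_instances) {
  mode <- match.arg(mode)
  rho_input <- match.arg(rho_input)
  stopifnot(inherits(w, "spatial_weights"))
  if (n_instances < 1) abort("`n_instances` must be >= 1.")
  if (abs(rho) >= 1) abort("|rho| must be < 1.")
  n <- w$n_areas
  k_lo <- floor(0.1 * n) + 1L
  k_hi <- n - 1L
  if (k_lo > k_hi) abort("N is too small for the k rule 0.1N < k < N.")
  seed <- check_seed(seed)
  W <- row_standardize(w)
  A <- if (rho != 0) Matrix::Diagonal(n) - rho * W else NULL
  if (rho_input == "estimate") w_eigenvalues(w) # warm the cache
  seeds <- derive_seeds(seed, max_attempts)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  kept_k <- integer(n_instances)
  kept_rho <- kept_m <- numeric(n_instances)
  kept <- 0L
  attempt <- 0L
  while (kept < n_instances) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      abort(sprintf(paste0(
        "attempt budget exhausted: %d of %d instances retained after %d ",
        "attempts (acceptance rate %.3f) for N = %d, rho = %.2f, mode = %s."),
        kept, n_instances, max_attempts, kept / max_attempts, n, rho, mode))
    }
    set.seed(seeds[[attempt]])
    eps <- rnorm(n)
    yv <- if (is.null(A)) eps else as.numeric(Matrix::solve(A, eps))
    k <- k_lo + sample.int(k_hi - k_lo + 1L, 1L) - 1L
    ok <- TRUE
    for (j in seq_len(r)) {
      vals <- dissolve_values(yv, grow_labels(w, k))
      p <- levene_stat(yv, vals)[["p.value"]]
      agree <- if (mode == "null") p >= alpha_levene else p < alpha_levene
      if (!agree) { ok <- FALSE; break }
    }
    if (!ok) next
    kept <- kept + 1L
    kept_k[kept] <- k
    rr <- if (rho_input == "estimate") estimate_rho_ml(yv, w)$rho_hat else rho
    kept_rho[kept] <- rr
    kept_m[kept] <- smaup_statistic(rr, k / n)
  }
  list(meta = tibble(k = kept_k, rho_used = kept_rho, m = kept_m),
       acceptance_rate = n_instances / attempt, attempts = attempt,
       seed = seed, rho_input = rho_input, n = n, rho = rho, r = r,
       alpha_levene = alpha_levene, mode = mode)
}

#' Simulate the null distribution of the S-maup statistic
#'
#' Builds the empirical distribution of the statistic under the null
#' hypothesis of non-sensitivity to the MAUP for a given lattice size and
#' autocorrelation level, by rejection sampling: a SAR variable and a region
#' count `k` (uniform on `0.1N < k < N`) are drawn, `r = 30` random
#' contiguous aggregations are formed, and the instance is retained only
#' when the Levene test of variance equality is *not* rejected in all 30
#' cases — i.e. only variables demonstrably unaffected by aggregation enter
#' the null. Each attempt uses a fresh variable and a fresh `k`.
#'
#' Percentiles of the retained statistic values are the test's critical
#' values; the packaged table was produced this way at `J = 1000` per
#' `(N, rho)` cell.
#'
#' @param w a [spatial_weights] object (or use `nrows`/`ncols` to build a
#'   rook lattice).
#' @param rho autocorrelation level of the simulated variables.
#' @param n_instances retained instances required (default 1000).
#' @param r aggregations per instance (default 30).
#' @param alpha_levene level of the screening Levene tests.
#' @param seed integer master seed.
#' @param rho_input `"label"` (default) evaluates the statistic at the
#'   generator's known `rho` — the quantity the tabulated critical values
#'   are indexed by; `"estimate"` instead plugs in the ML estimate of each
#'   retained variable's rho, as the applied test does.
#' @param nrows,ncols lattice dimensions, used when `w` is missing.
#' @param max_attempts attempt budget before failing with diagnostics.
#' @return An object of class `smaup_null`: list with `m_values`, per-
#'   instance `meta` (k, rho_used, m), `acceptance_rate`, `seed` and the
#'   generation parameters.
#' @export
generate_null <- function(w = NULL, rho, n_instances = 1000, r = 30,
                          alpha_levene = 0.05, seed = NULL,
                          rho_input = c("label", "estimate"),
                          nrows = NULL, ncols = NULL,
                          max_attempts = 1000 * n_instances) {
  if (is.null(w)) {
    if (is.null(nrows) || is.null(ncols)) {
      abort("supply `w` or both `nrows` and `ncols`.")
    }
    w <- rook_lattice(nrows, ncols)
  }
  res <- sample_instances(w, rho, n_instances, mode = "null", r = r,
                          alpha_levene = alpha_levene, seed = seed,
                          rho_input = rho_input, max_attempts = max_attempts)
  structure(list(m_values = res$meta$m, meta = res$meta, n = res$n,
                 rho = rho, r = r, alpha_levene = alpha_levene,
                 seed = res$seed, acceptance_rate = res$acceptance_rate,
                 rho_input = res$rho_input),
            class = "smaup_null")
}

#' @export
print.smaup_null <- function(x, ...) {
  q <- quantile(x$m_values, c(0.9, 0.95, 0.99), names = FALSE)
  cat(sprintf(
    "<smaup_null> N = %d, rho = %g, J = %d (rho input: %s)\n",
    x$n, x$rho, length(x$m_values), x$rho_input))
  cat(sprintf("  acceptance rate %.3f; percentiles 90/95/99: %.5f %.5f %.5f\n",
              x$acceptance_rate, q[1], q[2], q[3]))
  invisible(x)
}

#' Critical value from an empirical null
#'
#' The `(1 - alpha)` percentile of a simulated null, taken as the order
#' statistic `M_(ceiling((1 - alpha) * J))` so that, on the same null
#' vector, `M > null_quantile(null, alpha)` coincides with
#' `pseudo_p(M, null) < alpha` up to ties at the percentile.
#'
#' @param null a `smaup_null` object or numeric vector of null values.
#' @param alpha significance level.
#' @return the empirical critical value.
#' @export
null_quantile <- function(null, alpha = 0.05) {
  mj <- if (inherits(null, "smaup_null")) null$m_values else as.numeric(null)
  if (!length(mj)) abort("the null distribution is empty.")
  sort(mj)[ceiling((1 - alpha) * length(mj))]
}

#' @export
tidy.smaup_null <- function(x, ...) {
  x$meta
}

#' @export
glance.smaup_null <- function(x, ...) {
  tibble(n = x$n, rho = x$rho, J = length(x$m_values),
         acceptance_rate = x$acceptance_rate,
         q90 = null_quantile(x, 0.10), q95 = null_quantile(x, 0.05),
         q99 = null_quantile(x, 0.01))
}
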