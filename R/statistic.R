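# fitted constants of the statistic's calibrated response surface
smaup_constants <- c(b = -2.188, m = 7.031, p = 0.516, a = 1.287,
                     beta0 = 5.319, beta1 = -5.532)

#' Components of the S-maup statistic
#'
#' Evaluates the three calibrated component functions of the aggregation
#' level `theta = k / N`:
#' `L(theta) = 1 / (1 + exp(b + m * theta))` (the curve ceiling),
#' `eta(theta) = p * theta^a` (where the curve starts to decline) and
#' `tau(theta) = beta0 + beta1 * theta` (how fast it declines), with the
#' calibrated constants `b = -2.188`, `m = 7.031`, `p = 0.516`,
#' `a = 1.287`, `beta0 = 5.319`, `beta1 = -5.532`.
#'
#' @param theta aggregation level `k / N`, in `(0, 1]` (vectorised).
#' @return A tibble with columns `theta`, `L`, `eta`, `tau`.
#' @export
smaup_components <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta > 1)) {
    abort("`theta` must lie in (0, 1].")
  }
  cs <- smaup_constants
  tibble(theta = theta,
         L = 1 / (1 + exp(cs[["b"]] + cs[["m"]] * theta)),
         eta = cs[["p"]] * theta^cs[["a"]],
         tau = cs[["beta0"]] + cs[["beta1"]] * theta)
}

#' The S-maup statistic
#'
#' The inverted-logistic sensitivity measure
#' `M(rho, theta) = L(theta) / (1 + eta(theta) * exp(tau(theta) * rho))`,
#' which lies strictly between 0 and `L(theta) < 1`. Values near 1 indicate
#' that aggregating the variable into `k = theta * N` regions will distort
#' its distribution (high MAUP sensitivity); values near 0 indicate the
#' distribution is preserved.
#'
#' @param rho spatial autocorrelation of the variable, in `(-1, 1)`
#'   (vectorised).
#' @param theta aggregation level `k / N`, in `(0, 1]` (vectorised).
#' @return numeric vector of statistic values in `(0, 1)`.
#' @examples
#' smaup_statistic(rho = 0, theta = 0.4)
#' @export
smaup_statistic <- function(rho, theta) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    abort("`rho` must lie in (-1, 1).")
  }
  cmp <- smaup_components(theta)
  as.numeric(cmp$L / (1 + cmp$eta * exp(cmp$tau * rho)))
}

# packaged critical-value table, cached after first load
critical_table <- function() {
  if (is.null(the$crit)) {
    the$crit <- load_critical_table("packaged")
  }
  the$crit
}

#' Tabulated critical value of the S-maup test
#'
#' Looks up `M[alpha; rho, N]`, the `(1 - alpha)` percentile of the
#' statistic's Monte-Carlo null distribution, from the packaged table
#' (grid: `rho` in `{0, ±0.3, ±0.5, ±0.7, ±0.9}`, `N` in
#' `{25, 100, 225, 400, 625, 900}`, `alpha` in `{0.01, 0.05, 0.1}`).
#'
#' Off-grid `(rho, N)` pairs are resolved by an explicit policy:
#' `"interpolate"` (default) interpolates linearly along `rho` between the
#' bracketing grid rows and takes the nearest grid `N` (ties toward the
#' smaller `N`); `"conservative"` instead takes the larger of the two
#' bracketing `rho` cells. `rho` beyond ±0.9 uses the boundary row. The
#' policy actually applied is recorded in the `"policy"` attribute.
#'
#' @param rho spatial autocorrelation, in `(-1, 1)`.
#' @param N number of areas.
#' @param alpha significance level: one of 0.01, 0.05, 0.1.
#' @param method off-grid policy, `"interpolate"` or `"conservative"`.
#' @return the critical value, with attribute `policy`.
#' @export
critical_value <- function(rho, N, alpha = 0.05,
                           method = c("interpolate", "conservative")) {
  method <- match.arg(method)
  tab <- critical_table()
  alphas <- sort(unique(tab$alpha))
  if (!any(abs(alphas - alpha) < 1e-9)) {
    abort(paste0("`alpha` must be one of ", paste(alphas, collapse = ", "), "."))
  }
  tab <- tab[abs(tab$alpha - alpha) < 1e-9, ]
  ns <- sort(unique(tab$N))
  # nearest grid N, ties toward smaller
  dn <- abs(ns - N)
  n_use <- ns[which(dn == min(dn))][1]
  tab <- tab[tab$N == n_use, ]
  rhos <- sort(unique(tab$rho))
  r <- min(max(rho, min(rhos)), max(rhos))
  val_at <- function(rr) tab$value[abs(tab$rho - rr) < 1e-9]
  if (any(abs(rhos - r) < 1e-9)) {
    policy <- if (n_use == N && r == rho) "exact" else "nearest-N/clamped-rho"
    out <- val_at(rhos[abs(rhos - r) < 1e-9][1])
  } else {
    lo <- max(rhos[rhos < r]); hi <- min(rhos[rhos > r])
    if (method == "interpolate") {
      f <- (r - lo) / (hi - lo)
      out <- (1 - f) * val_at(lo) + f * val_at(hi)
      policy <- sprintf("rho-interpolated [%g, %g], N = %d", lo, hi, n_use)
    } else {
      out <- max(val_at(lo), val_at(hi))
      policy <- sprintf("conservative max of rho in {%g, %g}, N = %d", lo, hi, n_use)
    }
  }
  structure(out, policy = policy)
}

#' Pseudo-p value against an empirical null
#'
#' `P(M) = (1/J) * sum_j 1[M_j > M]`: the fraction of null-simulated
#' statistic values strictly exceeding the observed one.
#'
#' @param M observed statistic value.
#' @param null a `smaup_null` object from [generate_null()] or a numeric
#'   vector of null statistic values.
#' @return the pseudo-p value in `[0, 1]`.
#' @export
pseudo_p <- function(M, null) {
  mj <- if (inherits(null, "smaup_null")) null$m_values else as.numeric(null)
  if (!length(mj)) abort("the null distribution is empty.")
  mean(mj > M)
}
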