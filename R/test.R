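#' S-maup test of sensitivity to the modifiable areal unit problem
#'
#' Tests the null hypothesis that the areal variable `y` is *not*
#' significantly affected by the MAUP when its `N` areas are aggregated into
#' `k` contiguous regions. The spatial autocorrelation is estimated from the
#' data by SAR maximum likelihood, the statistic
#' `M = smaup_statistic(rho_hat, k / N)` is evaluated, and the null is
#' rejected when `M` exceeds the tabulated critical value
#' `M[alpha; rho, N]`. When an empirical null is supplied, a pseudo-p value
#' is reported as well.
#'
#' @param y areal variable: tibble `(area_id, value)` or numeric vector.
#' @param w a [spatial_weights] object.
#' @param k number of regions considered, `1 <= k < N`.
#' @param alpha significance level (0.01, 0.05 or 0.1 for the tabulated
#'   critical values).
#' @param null optional `smaup_null` from [generate_null()] for a pseudo-p.
#' @param cv_method off-grid critical-value policy, see [critical_value()].
#' @return An object of class `smaup_test` with fields `rho_hat`, `n`, `k`,
#'   `theta`, `statistic`, `critical_value`, `alpha`, `reject`, `pseudo_p`
#'   (NA without a null). Supports [tidy()], [glance()] and `print()`.
#' @examples
#' w <- rook_lattice(10, 10)
#' y <- simulate_sar(w, rho = 0.5, seed = 7)
#' smaup_test(y, w, k = 30)
#' @export
smaup_test <- function(y, w, k, alpha = 0.05, null = NULL,
                       cv_method = c("interpolate", "conservative")) {
  cv_method <- match.arg(cv_method)
  n <- n_areas(w)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k >= n) {
    abort("`k` must be smaller than the number of areas (and at least 1).")
  }
  est <- estimate_rho_ml(y, w)
  theta <- k / n
  M <- smaup_statistic(est$rho_hat, theta)
  cv <- critical_value(est$rho_hat, n, alpha, method = cv_method)
  pp <- if (!is.null(null)) pseudo_p(M, null) else NA_real_
  structure(list(rho_hat = est$rho_hat, moran_i = est$moran_i, n = n, k = k,
                 theta = theta, statistic = M,
                 critical_value = as.numeric(cv),
                 cv_policy = attr(cv, "policy"), alpha = alpha,
                 reject = M > as.numeric(cv), pseudo_p = pp),
            class = "smaup_test")
}

#' @export
print.smaup_test <- function(x, ...) {
  cat("\n\tS-maup test of MAUP sensitivity\n\n")
  cat(sprintf("N = %d areas into k = %d regions (theta = %.4f)\n",
              x$n, x$k, x$theta))
  cat(sprintf("rho_hat = %.4f (SAR ML), M = %.5f, critical value = %.5f (alpha = %g)\n",
              x$rho_hat, x$statistic, x$critical_value, x$alpha))
  if (!is.na(x$pseudo_p)) cat(sprintf("pseudo-p = %.3f\n", x$pseudo_p))
  cat(if (x$reject) {
    "H0 rejected: the variable is sensitive to the MAUP at this aggregation level.\n"
  } else {
    "H0 not rejected: no evidence of MAUP sensitivity at this aggregation level.\n"
  })
  invisible(x)
}

#' @export
tidy.smaup_test <- function(x, ...) {
  tibble(rho_hat = x$rho_hat, n = x$n, k = x$k, theta = x$theta,
         statistic = x$statistic, critical_value = x$critical_value,
         alpha = x$alpha, pseudo_p = x$pseudo_p, reject = x$reject)
}

#' @export
glance.smaup_test <- function(x, ...) {
  tidy(x)
}

#' Scan aggregation levels for the maximum safe aggregation
#'
#' Runs the S-maup test over a grid of region counts for one or more
#' variables and reports, per variable, the smallest `k` at which the test
#' fails to reject (the heaviest aggregation that preserves the variable's
#' distribution). For several variables — e.g. all regressors of a model —
#' the headline value is the maximum of the per-variable minima: the level
#' at which *every* variable keeps its distributional characteristics.
#'
#' @param ys a single areal variable or a (possibly named) list of them.
#' @param w a [spatial_weights] object.
#' @param k_grid increasing vector of region counts, all `< N`.
#' @param alpha significance level.
#' @param cv_method off-grid critical-value policy, see [critical_value()].
#' @return An object of class `smaup_scan`: list with `table` (variable, k,
#'   rho_hat, theta, statistic, critical_value, reject), `per_variable`
#'   (minimum safe k per variable) and `k_safe` (the headline k). If some
#'   variable rejects at every grid k the function aborts with a condition
#'   of class `smaup_no_safe_k` carrying the scan table.
#' @export
k_scan <- function(ys, w, k_grid, alpha = 0.05,
                   cv_method = c("interpolate", "conservative")) {
  cv_method <- match.arg(cv_method)
  n <- n_areas(w)
  if (is.data.frame(ys) || is.numeric(ys)) ys <- list(ys)
  if (is.null(names(ys)) || any(names(ys) == "")) {
    names(ys) <- paste0("y", seq_along(ys))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid >= n)) {
    abort("all grid k must satisfy 1 <= k < N.")
  }
  tab <- purrr::map_dfr(names(ys), function(nm) {
    est <- estimate_rho_ml(ys[[nm]], w)
    cvs <- vapply(k_grid, function(k) {
      as.numeric(critical_value(est$rho_hat, n, alpha, method = cv_method))
    }, numeric(1))
    M <- smaup_statistic(est$rho_hat, k_grid / n)
    tibble(variable = nm, k = k_grid, rho_hat = est$rho_hat,
           theta = k_grid / n, statistic = M, critical_value = cvs,
           reject = M > cvs)
  })
  per_var <- tab |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      k_min = if (any(!.data$reject)) min(.data$k[!.data$reject]) else NA_integer_,
      .groups = "drop")
  if (any(is.na(per_var$k_min))) {
    bad <- per_var$variable[is.na(per_var$k_min)]
    abort(paste0("no safe aggregation level: variable(s) ",
                 paste(bad, collapse = ", "),
                 " reject at every k in the grid."),
          class = "smaup_no_safe_k", scan_table = tab)
  }
  structure(list(table = tab, per_variable = per_var,
                 k_safe = max(per_var$k_min), alpha = alpha),
            class = "smaup_scan")
}

#' @export
print.smaup_scan <- function(x, ...) {
  cat(sprintf("<smaup_scan> alpha = %g\n", x$alpha))
  print(x$per_variable)
  cat(sprintf("maximum safe aggregation: k = %d (all variables retain their distribution)\n",
              x$k_safe))
  invisible(x)
}

#' @export
tidy.smaup_scan <- function(x, ...) {
  x$table
}

#' @export
glance.smaup_scan <- function(x, ...) {
  tibble(k_safe = x$k_safe, alpha = x$alpha,
         n_variables = nrow(x$per_variable))
}
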