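#' Power and size of the S-maup test by simulation
#'
#' `power_experiment()` estimates the test's power: SAR variables are
#' screened so that only instances demonstrably *affected* by aggregation
#' enter (the Levene test rejects for all `r = 30` random aggregations at
#' the drawn `k`), and the proportion of retained instances whose statistic
#' exceeds the critical value is returned. `size_experiment()` estimates the
#' empirical size with the complementary screening (Levene not rejected in
#' all 30 cases — the null regime).
#'
#' The critical value defaults to the packaged table looked up at the
#' generator's `rho` label; pass `critical` to override (e.g. with a
#' percentile of a same-generator null from [null_quantile()]). The
#' statistic itself is evaluated at the generator's rho label by default
#' (the simulation knows the true rho, which also indexes the critical
#' values), switchable to the per-instance ML estimate.
#'
#' @param w a [spatial_weights] object (or `nrows`/`ncols` for a rook
#'   lattice).
#' @param rho autocorrelation level of the simulated variables.
#' @param n_instances retained instances (1000 in the full experiments).
#' @param alpha significance level.
#' @param seed integer master seed.
#' @param critical optional critical value overriding the table lookup.
#' @param rho_input `"estimate"` or `"label"`; see [generate_null()].
#' @param r aggregations per instance.
#' @param nrows,ncols lattice dimensions, used when `w` is missing.
#' @param max_attempts attempt budget before failing with diagnostics.
#' @return A one-row tibble with `proportion_reject`, `n_instances`,
#'   `critical_value`, `acceptance_rate`, `seed` and the parameters.
#' @export
power_experiment <- function(w = NULL, rho, n_instances = 1000, alpha = 0.05,
                             seed = NULL, critical = NULL,
                             rho_input = c("label", "estimate"), r = 30,
                             nrows = NULL, ncols = NULL,
                             max_attempts = 1000 * n_instances) {
  rejection_experiment(w, rho, n_instances, alpha, seed, critical, rho_input,
                       r, nrows, ncols, max_attempts, mode = "alt")
}

#' @rdname power_experiment
#' @export
size_experiment <- function(w = NULL, rho, n_instances = 1000, alpha = 0.05,
                            seed = NULL, critical = NULL,
                            rho_input = c("label", "estimate"), r = 30,
                            nrows = NULL, ncols = NULL,
                            max_attempts = 1000 * n_instances) {
  rejection_experiment(w, rho, n_instances, alpha, seed, critical, rho_input,
                       r, nrows, ncols, max_attempts, mode = "null")
}

rejection_experiment <- function(w, rho, n_instances, alpha, seed, critical,
                                 rho_input, r, nrows, ncols, max_attempts,
                                 mode) {
  rho_input <- match.arg(rho_input, c("label", "estimate"))
  if (is.null(w)) {
    if (is.null(nrows) || is.null(ncols)) {
      abort("supply `w` or both `nrows` and `ncols`.")
    }
    w <- rook_lattice(nrows, ncols)
  }
  res <- sample_instances(w, rho, n_instances, mode = mode, r = r,
                          alpha_levene = alpha, seed = seed,
                          rho_input = rho_input, max_attempts = max_attempts)
  cv <- if (is.null(critical)) {
    as.numeric(critical_value(rho, w$n_areas, alpha))
  } else as.numeric(critical)
  tibble(proportion_reject = mean(res$meta$m > cv),
         n_instances = n_instances, n_areas = w$n_areas, rho = rho,
         alpha = alpha, critical_value = cv,
         acceptance_rate = res$acceptance_rate, rho_input = rho_input,
         mode = mode, seed = res$seed)
}

#' Recalibrate the statistic's constants from effect medians
#'
#' Fits the six constants of the statistic's response surface to a table of
#' median mean-RCV effects indexed by autocorrelation `rho` and aggregation
#' level `theta`, reproducing the calibration pipeline at any scale:
#'
#' 1. each `theta`-curve `med(rho)` is fitted with the three-parameter
#'    inverted logistic `L / (1 + eta * exp(tau * rho))` by nonlinear least
#'    squares ([minpack.lm::nlsLM()]), initialised from the curve's maximum
#'    (for `L`) and the linearised log-ratio regression (for `eta`, `tau`);
#' 2. a robust (Huber IRLS, [MASS::rlm()]) linear fit of
#'    `log((1 - L) / L) = b + m * theta` gives `b` and `m`;
#' 3. a robust log-log fit `log(eta) = log(p) + a * log(theta)` gives `p`
#'    and `a`, and a robust linear fit `tau = beta0 + beta1 * theta` gives
#'    `beta0` and `beta1`;
#' 4. the six constants are jointly refined by nonlinear least squares on
#'    the full `(rho, theta)` grid, with weights `1 / median^2` (relative
#'    error — appropriate for the multiplicative dispersion of Monte-Carlo
#'    medians), started from the staged estimates.
#'
#' On noiseless medians generated from the closed form the pipeline is
#' exact; see the methods vignette for why per-curve `L` is refined by the
#' nonlinear fit rather than read off the curve maximum, and why the joint
#' refinement stage exists.
#'
#' @param effect_medians data frame with columns `rho`, `theta` and
#'   `median_rcv`, covering at least 5 `theta` values and the full rho grid.
#' @return An object of class `smaup_calibration`: list with `constants`
#'   (named vector b, m, p, a, beta0, beta1, after joint refinement),
#'   `staged_constants` (before refinement), `curve_fits` (per-theta L,
#'   eta, tau), and `r_squared` for the three linearised stages. Supports
#'   [tidy()] and [glance()].
#' @export
fit_components <- function(effect_medians) {
  d <- as_tibble(effect_medians)
  if (!all(c("rho", "theta", "median_rcv") %in% names(d))) {
    abort("`effect_medians` needs columns rho, theta, median_rcv.")
  }
  thetas <- sort(unique(d$theta))
  if (length(thetas) < 5) abort("need medians for at least 5 theta values.")
  curve <- purrr::map_dfr(thetas, function(th) {
    dd <- d[d$theta == th, ]
    if (nrow(dd) < 4) abort("each theta curve needs at least 4 rho points.")
    fit <- fit_inverted_logistic(dd$rho, dd$median_rcv)
    tibble(theta = th, L = fit[["L"]], eta = fit[["eta"]], tau = fit[["tau"]])
  })
  # stage 2: logit-linear robust fit for (b, m)
  ylog <- log((1 - curve$L) / curve$L)
  f1 <- MASS::rlm(ylog ~ curve$theta, maxit = 100)
  b <- unname(coef(f1)[1]); m <- unname(coef(f1)[2])
  # stage 3: log-log robust fit for (p, a); linear robust fit for (beta0, beta1)
  f2 <- MASS::rlm(log(curve$eta) ~ log(curve$theta), maxit = 100)
  p <- exp(unname(coef(f2)[1])); a <- unname(coef(f2)[2])
  f3 <- MASS::rlm(curve$tau ~ curve$theta, maxit = 100)
  beta0 <- unname(coef(f3)[1]); beta1 <- unname(coef(f3)[2])
  r2 <- function(f, y) 1 - sum(resid(f)^2) / sum((y - mean(y))^2)
  staged <- c(b = b, m = m, p = p, a = a, beta0 = beta0, beta1 = beta1)
  # stage 4: joint relative-error refinement on the full grid
  joint <- try(minpack.lm::nlsLM(
    median_rcv ~ (1 / (1 + exp(b + m * theta))) /
      (1 + p * theta^a * exp((beta0 + beta1 * theta) * rho)),
    data = d, start = as.list(staged), weights = 1 / d$median_rcv^2,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)), silent = TRUE)
  constants <- if (inherits(joint, "try-error")) staged else coef(joint)[names(staged)]
  structure(list(
    constants = constants,
    staged_constants = staged,
    curve_fits = curve,
    r_squared = c(logistic = r2(f1, ylog),
                  power = r2(f2, log(curve$eta)),
                  linear = r2(f3, curve$tau))),
    class = "smaup_calibration")
}

# one theta-curve: med(rho) = L / (1 + eta * exp(tau * rho))
fit_inverted_logistic <- function(rho, med) {
  L0 <- max(med)
  # linearised start: log(L0' / med - 1) ~ log(eta) + tau * rho, with the
  # ceiling slightly inflated so the maximum point stays in the domain
  Li <- L0 * 1.02
  g <- log(pmax(Li / med - 1, 1e-12))
  st <- coef(lm(g ~ rho))
  start <- list(L = min(L0 * 1.01, 0.999), eta = max(exp(st[[1]]), 1e-10),
                tau = st[[2]])
  dat <- data.frame(rho = rho, med = med)
  fit <- try(minpack.lm::nlsLM(
    med ~ L / (1 + eta * exp(tau * rho)), data = dat, start = start,
    lower = c(L = 1e-8, eta = 1e-12, tau = -60),
    upper = c(L = 1 - 1e-8, eta = 1e4, tau = 60),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    abort(paste0("per-curve nonlinear fit failed: ", attr(fit, "condition")$message))
  }
  cf <- coef(fit)
  c(L = unname(cf[["L"]]), eta = unname(cf[["eta"]]), tau = unname(cf[["tau"]]))
}

#' @export
print.smaup_calibration <- function(x, ...) {
  cat("<smaup_calibration>\n  constants:\n")
  print(round(x$constants, 4))
  cat("  linearised-stage R-squared:\n")
  print(round(x$r_squared, 4))
  invisible(x)
}

#' @export
tidy.smaup_calibration <- function(x, ...) {
  tibble(term = names(x$constants), estimate = unname(x$constants))
}

#' @export
glance.smaup_calibration <- function(x, ...) {
  tibble(r2_logistic = x$r_squared[["logistic"]],
         r2_power = x$r_squared[["power"]],
         r2_linear = x$r_squared[["linear"]],
         n_curves = nrow(x$curve_fits))
}
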