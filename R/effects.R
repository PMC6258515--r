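#' Relative change between an original and an aggregated summary
#'
#' `|orig - agg| / |orig|` — the relative change in the mean (RCM) or in the
#' variance (RCV) between the disaggregated variable and one aggregated
#' version of it. The numerator is unsigned and the denominator is the
#' magnitude of the original summary, so the measure is non-negative also
#' for variables whose mean is negative (a SAR draw is mean-zero in
#' expectation, so either sign occurs).
#'
#' @param orig summary of the original variable (non-zero).
#' @param agg summary of the aggregated variable.
#' @param kind `"mean"` or `"variance"`; informational only, the formula is
#'   identical.
#' @return non-negative numeric (vectorised over `orig`/`agg`).
#' @export
relative_change <- function(orig, agg, kind = c("mean", "variance")) {
  match.arg(kind)
  if (any(orig == 0)) abort("relative change is undefined for a zero original value.")
  abs(orig - agg) / abs(orig)
}

#' Summarise per-replicate MAUP effects
#'
#' Averages the per-replicate relative changes in the mean and in the
#' variance over the `r` random aggregations of one experiment instance.
#'
#' @param rcm_per_rep,rcv_per_rep numeric vectors of equal length `r >= 1`.
#' @return A one-row tibble with `mean_rcm`, `mean_rcv` and `r`.
#' @export
summarize_effects <- function(rcm_per_rep, rcv_per_rep) {
  if (!length(rcm_per_rep) || !length(rcv_per_rep)) {
    abort("effect summaries need at least one replicate.")
  }
  if (length(rcm_per_rep) != length(rcv_per_rep)) {
    abort("RCM and RCV vectors must have the same length.")
  }
  tibble(mean_rcm = mean(rcm_per_rep), mean_rcv = mean(rcv_per_rep),
         r = length(rcm_per_rep))
}

# two-group Levene statistic with mean centring, as bare numbers (hot path):
# Z_ij = |y_ij - mean_i|, W = (N-2) * sum_i n_i (Zbar_i - Zbar)^2 /
# sum_ij (Z_ij - Zbar_i)^2, p from F(1, N-2)
levene_stat <- function(a, b) {
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  n1 <- length(za); n2 <- length(zb); n <- n1 + n2
  m1 <- mean(za); m2 <- mean(zb)
  mg <- (n1 * m1 + n2 * m2) / n
  between <- n1 * (m1 - mg)^2 + n2 * (m2 - mg)^2
  within <- sum((za - m1)^2) + sum((zb - m2)^2)
  if (within == 0) {
    if (between == 0) return(c(statistic = 0, p.value = 1))
    return(c(statistic = Inf, p.value = 0))
  }
  stat <- (n - 2) * between / within
  c(statistic = stat, p.value = pf(stat, 1, n - 2, lower.tail = FALSE))
}

# Welch two-sample t statistic with Satterthwaite df, two-sided p (hot path)
welch_stat <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(c(statistic = 0, p.value = 1))
    return(c(statistic = Inf, p.value = 0))
  }
  stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(statistic = stat, p.value = 2 * pt(-abs(stat), df))
}

#' Two-sample Levene test for equality of variances
#'
#' Classical (mean-centred) Levene test: absolute deviations from each
#' group's mean are compared by a one-way ANOVA F statistic on 1 and
#' `N - 2` degrees of freedom. Median centring (Brown-Forsythe) is
#' available via `center = "median"`.
#'
#' If both groups have zero spread around their centres the statistic is 0
#' and `p = 1` by convention.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param center `"mean"` (classical, default) or `"median"`
#'   (Brown-Forsythe).
#' @return An object of class `htest`.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(a) < 2 || length(b) < 2) abort("each sample needs length >= 2.")
  if (center == "median") {
    za <- abs(a - median(a)); zb <- abs(b - median(b))
    res <- levene_center_free(za, zb)
  } else {
    res <- levene_stat(a, b)
  }
  structure(list(statistic = c(W = unname(res["statistic"])),
                 parameter = c(df1 = 1, df2 = length(a) + length(b) - 2),
                 p.value = unname(res["p.value"]),
                 method = sprintf("Two-sample Levene test (%s centring)", center),
                 data.name = paste(deparse(substitute(a)), "and",
                                   deparse(substitute(b)))),
            class = "htest")
}

# ANOVA on already-centred absolute deviations
levene_center_free <- function(za, zb) {
  n1 <- length(za); n2 <- length(zb); n <- n1 + n2
  m1 <- mean(za); m2 <- mean(zb)
  mg <- (n1 * m1 + n2 * m2) / n
  between <- n1 * (m1 - mg)^2 + n2 * (m2 - mg)^2
  within <- sum((za - m1)^2) + sum((zb - m2)^2)
  if (within == 0) {
    if (between == 0) return(c(statistic = 0, p.value = 1))
    return(c(statistic = Inf, p.value = 0))
  }
  stat <- (n - 2) * between / within
  c(statistic = stat, p.value = pf(stat, 1, n - 2, lower.tail = FALSE))
}

#' Welch two-sample t test
#'
#' Two-sided Welch test of equality of means with Satterthwaite degrees of
#' freedom. Welch's form is the package default because aggregation changes
#' the variance — the very effect under study — so pooled variances cannot
#' be assumed; `var_equal = TRUE` switches to the pooled test.
#'
#' @inheritParams levene_test
#' @param var_equal use the pooled-variance form instead of Welch.
#' @return An object of class `htest`.
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs length >= 2.")
  if (var_equal) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    if (se2 == 0) {
      res <- if (mean(a) == mean(b)) c(statistic = 0, p.value = 1)
             else c(statistic = Inf, p.value = 0)
      df <- n1 + n2 - 2
    } else {
      stat <- (mean(a) - mean(b)) / sqrt(se2)
      df <- n1 + n2 - 2
      res <- c(statistic = stat, p.value = 2 * pt(-abs(stat), df))
    }
  } else {
    res <- welch_stat(a, b)
    v1 <- var(a) / length(a); v2 <- var(b) / length(b)
    df <- if (v1 + v2 == 0) NA_real_ else
      (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  }
  structure(list(statistic = c(t = unname(res["statistic"])),
                 parameter = c(df = unname(df)),
                 p.value = unname(res["p.value"]),
                 method = if (var_equal) "Two-sample t test (pooled variance)"
                          else "Welch two-sample t test",
                 data.name = paste(deparse(substitute(a)), "and",
                                   deparse(substitute(b)))),
            class = "htest")
}

#' Experiment configuration
#'
#' Bundles the parameter grid of the aggregation-effect experiment. The
#' defaults are the full study conditions: lattice sizes
#' `N = {25, 100, 225, 400, 625, 900}`, their region-count sets, the
#' autocorrelation grid `{-0.9, ..., 0.9}`, `i = 50` instances per level and
#' `r = 30` random aggregations per instance. Scaled-down runs shrink
#' `n_values` and `instances`, never `r`.
#'
#' @param n_values lattice sizes (perfect squares).
#' @param k_sets named list mapping each `N` to its set of region counts.
#' @param rho_grid spatial autocorrelation labels.
#' @param instances SAR instances per `(N, rho)` level.
#' @param r random aggregations per instance.
#' @param alpha significance level for the Levene and t tests.
#' @param seed master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_values = c(25, 100, 225, 400, 625, 900),
                              k_sets = default_k_sets(),
                              rho_grid = c(-0.9, -0.7, -0.5, -0.3, 0,
                                           0.3, 0.5, 0.7, 0.9),
                              instances = 50, r = 30, alpha = 0.05,
                              seed = NULL) {
  if (!all(as.character(n_values) %in% names(k_sets))) {
    abort("every N in `n_values` needs an entry in `k_sets`.")
  }
  for (nn in n_values) {
    if (any(k_sets[[as.character(nn)]] >= nn)) {
      abort("all K entries must be smaller than their N.")
    }
  }
  structure(list(n_values = n_values, k_sets = k_sets, rho_grid = rho_grid,
                 instances = instances, r = r, alpha = alpha,
                 seed = check_seed(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
default_k_sets <- function() {
  list(`25` = c(3, 5, 10, 13, 15, 18, 20, 22, 24),
       `100` = c(2, 4, 7, 12, 25, 40, 53, 67, 80, 90, 99),
       `225` = c(3, 5, 10, 15, 30, 60, 90, 120, 150, 180, 200, 220),
       `400` = c(4, 9, 18, 26, 50, 110, 160, 213, 267, 320, 360, 396),
       `625` = c(4, 6, 14, 27, 43, 80, 170, 250, 333, 417, 500, 563, 618),
       `900` = c(4, 9, 20, 40, 60, 120, 240, 360, 480, 600, 720, 810, 890))
}

# effects of r aggregations of one variable at one k (hot path)
aggregate_effects <- function(yv, w, k, r, seed) {
  mu_o <- mean(yv); s2_o <- var_pop(yv)
  seeds <- derive_seeds(seed, r)
  rcm <- rcv <- lev_p <- t_p <- numeric(r)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (j in seq_len(r)) {
    set.seed(seeds[[j]])
    vals <- dissolve_values(yv, grow_labels(w, k))
    rcm[j] <- abs(mu_o - mean(vals)) / abs(mu_o)
    rcv[j] <- abs(s2_o - var_pop(vals)) / s2_o
    lev_p[j] <- levene_stat(yv, vals)[["p.value"]]
    t_p[j] <- welch_stat(yv, vals)[["p.value"]]
  }
  list(rcm = rcm, rcv = rcv, levene_p = lev_p, t_p = t_p)
}

#' Run the aggregation-effect experiment grid
#'
#' For each lattice size `N`, autocorrelation label `rho` and instance, one
#' SAR variable is produced (a base draw at `rho = 0.9`, rank-matched onto a
#' fresh pattern for every other label so that all labels share one value
#' multiset), then aggregated `r` times into each `k` of the size's region
#' set. Per `(N, rho, k, instance)` the mean relative changes in mean and
#' variance and the Levene / Welch rejection counts are recorded.
#'
#' The pooled t-test rejection proportion — the experiment's headline number
#' — is computed over aggregations with `k >= 10` only, mirroring how the
#' mean effect is customarily reported; the Levene pool uses all `k`.
#'
#' @param config an [experiment_config()].
#' @return A tibble with one row per `(N, rho, k, instance)` and columns
#'   `mean_rcm`, `mean_rcv`, `levene_rejections`, `t_rejections`, `r`,
#'   `rho_hat`, `mu_o`, `sigma2_o`; attributes `pooled` (rejection
#'   proportions, the t pool restricted to `k >= 10`) and `config`. Note
#'   that `mean_rcm` divides by `|mu_o|`, which for a mean-zero generator
#'   is a near-zero random quantity: judge the mean effect via the t pool
#'   or via `mean_rcm * abs(mu_o) / sqrt(sigma2_o)` (change in units of the
#'   variable's spread).
#' @export
effect_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  base_rho <- 0.9
  n_seeds <- derive_seeds(config$seed, length(config$n_values))
  for (ni in seq_along(config$n_values)) {
    nn <- config$n_values[[ni]]
    side <- as.integer(round(sqrt(nn)))
    if (side * side != nn) abort("lattice sizes must be perfect squares.")
    w <- rook_lattice(side, side)
    ks <- config$k_sets[[as.character(nn)]]
    ks <- ks[ks >= 1 & ks <= nn]
    inst_seeds <- derive_seeds(n_seeds[[ni]], config$instances)
    for (i in seq_len(config$instances)) {
      nrho <- length(config$rho_grid)
      sub <- derive_seeds(inst_seeds[[i]], 1L + 2L * nrho)
      base <- simulate_sar(w, base_rho, sub[[1L]])
      for (ri in seq_along(config$rho_grid)) {
        rho <- config$rho_grid[[ri]]
        yy <- if (rho == base_rho) base else
          retarget_rho(base, w, rho, seed = sub[[1L + ri]])
        yv <- as_area_values(yy, w)
        rho_hat <- attr(yy, "rho_hat") %||% estimate_rho_ml(yv, w)$rho_hat
        agg_seeds <- derive_seeds(sub[[1L + nrho + ri]], length(ks))
        for (ki in seq_along(ks)) {
          k <- ks[[ki]]
          eff <- aggregate_effects(yv, w, k, config$r, seed = agg_seeds[[ki]])
          rows[[length(rows) + 1L]] <- tibble(
            n_areas = nn, rho = rho, k = k, instance = i,
            mean_rcm = mean(eff$rcm), mean_rcv = mean(eff$rcv),
            levene_rejections = sum(eff$levene_p < config$alpha),
            t_rejections = sum(eff$t_p < config$alpha),
            r = config$r, rho_hat = rho_hat,
            mu_o = mean(yv), sigma2_o = var_pop(yv))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  pool_t <- dplyr::filter(out, .data$k >= 10)
  pooled <- tibble(
    t_rejection_proportion = sum(pool_t$t_rejections) / (nrow(pool_t) * config$r),
    levene_rejection_proportion = sum(out$levene_rejections) / (nrow(out) * config$r),
    t_pool_k_min = 10)
  structure(out, pooled = pooled, config = config,
            class = c("maup_effects", class(out)))
}

#' @export
glance.maup_effects <- function(x, ...) {
  attr(x, "pooled")
}
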