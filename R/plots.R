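#' Map an areal variable on its lattice
#'
#' Tile map of a variable over a rook lattice (row 0 at the top), useful for
#' eyeballing the spatial pattern produced by [simulate_sar()] or
#' [retarget_rho()], or a partition from [grow_regions()] (pass the
#' `region_id` column as the fill).
#'
#' @param y areal variable: tibble `(area_id, value)` or numeric vector.
#' @param w a [spatial_weights] object built by [rook_lattice()] (its
#'   dimensions are taken from the object), or supply `nrows`/`ncols`.
#' @param nrows,ncols lattice dimensions when `w` carries none.
#' @return A ggplot object.
#' @export
plot_area_values <- function(y, w = NULL, nrows = NULL, ncols = NULL) {
  if (!is.null(w) && !is.null(w$lattice_dims)) {
    nrows <- w$lattice_dims[1]; ncols <- w$lattice_dims[2]
  }
  if (is.null(nrows) || is.null(ncols)) {
    abort("lattice dimensions are needed: pass a lattice `w` or nrows/ncols.")
  }
  v <- if (is.data.frame(y)) y$value[order(y$area_id)] else as.numeric(y)
  d <- tibble(row = rep(seq_len(nrows), each = ncols),
              col = rep(seq_len(ncols), nrows),
              value = v)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smaup_null <- function(object, ...) {
  d <- tibble(m = object$m_values)
  q <- tibble(alpha = c(0.1, 0.05, 0.01),
              cv = vapply(c(0.1, 0.05, 0.01),
                          function(a) null_quantile(object, a), numeric(1)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = q,
                        ggplot2::aes(xintercept = .data$cv,
                                     linetype = factor(.data$alpha))) +
    ggplot2::labs(x = "S-maup statistic under H0", y = "count",
                  linetype = "alpha",
                  title = sprintf("Empirical null (N = %d, rho = %g, J = %d)",
                                  object$n, object$rho,
                                  length(object$m_values))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smaup_scan <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$k, y = .data$statistic,
                               colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$critical_value),
                       linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$k_safe, linetype = "dotted") +
    ggplot2::labs(x = "number of regions k", y = "S-maup statistic",
                  title = sprintf("k-scan (safe aggregation at k = %d)",
                                  object$k_safe)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smaup_test <- function(object, ...) {
  rho <- seq(-0.95, 0.95, by = 0.01)
  d <- tibble(rho = rho, M = smaup_statistic(rho, object$theta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho, y = .data$M)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$critical_value,
                        linetype = "dashed") +
    ggplot2::annotate("point", x = object$rho_hat, y = object$statistic,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "spatial autocorrelation rho",
                  y = sprintf("S-maup statistic at theta = %.3f", object$theta),
                  title = sprintf("M = %.4f vs critical value %.4f (%s)",
                                  object$statistic, object$critical_value,
                                  if (object$reject) "reject H0" else
                                    "fail to reject H0")) +
    ggplot2::theme_minimal()
}
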