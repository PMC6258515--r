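#' Random contiguous aggregation by seed-based region growing
#'
#' Partitions the `n` areas of `w` into `k` spatially contiguous regions:
#' `k` distinct seed areas are drawn uniformly at random, then unassigned
#' areas adjacent to a growing region are repeatedly picked uniformly at
#' random and attached to a uniformly random adjacent region until every
#' area is assigned. Each region's induced subgraph is connected by
#' construction, and the same `(w, k, seed)` always gives the same
#' partition.
#'
#' @param w a [spatial_weights] object (must be connected, which the
#'   constructor guarantees).
#' @param k number of regions, `1 <= k <= n`.
#' @param seed integer seed.
#' @return A tibble `(area_id, region_id)` (both 0-based) with attributes
#'   `k` and `seed`.
#' @examples
#' w <- rook_lattice(6, 6)
#' agg <- grow_regions(w, k = 5, seed = 1)
#' table(agg$region_id)
#' @export
grow_regions <- function(w, k, seed = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- w$n_areas
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) {
    abort(sprintf("`k` must be an integer in [1, %d].", n))
  }
  seed <- check_seed(seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lab <- grow_labels(w, k)
  structure(tibble(area_id = 0:(n - 1L), region_id = lab),
            k = k, seed = seed,
            class = c("tbl_df", "tbl", "data.frame"))
}

# bare labels under the current RNG state (hot path; no tibble, no set.seed)
grow_labels <- function(w, k) {
  nbr0 <- w$cache$nbr0
  if (is.null(nbr0)) {
    nbr0 <- lapply(w$neighbors, function(v) v - 1L)
    w$cache$nbr0 <- nbr0
  }
  grow_regions_cpp(nbr0, k)
}

# labels from an aggregation tibble (or bare integer vector), in id order
as_region_labels <- function(agg, n = NULL) {
  if (is.data.frame(agg)) {
    if (!all(c("area_id", "region_id") %in% names(agg))) {
      abort("aggregations need columns `area_id` and `region_id`.")
    }
    lab <- as.integer(agg$region_id)[order(as.integer(agg$area_id))]
  } else {
    lab <- as.integer(agg)
  }
  if (!is.null(n) && length(lab) != n) {
    abort("aggregation length does not match the variable.")
  }
  lab
}

#' Dissolve an areal variable onto regions by unweighted means
#'
#' The value of each region is the unweighted arithmetic mean of its member
#' areas' values — the defining behaviour of a spatially intensive variable
#' (rate, density, proportion) under aggregation.
#'
#' @param y areal variable: tibble `(area_id, value)` or numeric vector.
#' @param agg an aggregation from [grow_regions()] (or an integer label
#'   vector in area-id order).
#' @return A tibble `(region_id, value)` with attributes `mu_ag` and
#'   `sigma2_ag` (mean and population variance of the `k` region values).
#' @export
dissolve_mean <- function(y, agg) {
  yv <- if (is.data.frame(y)) {
    as.numeric(y$value)[order(as.integer(y$area_id))]
  } else as.numeric(y)
  lab <- as_region_labels(agg)
  if (length(lab) != length(yv)) abort("aggregation length does not match the variable.")
  vals <- dissolve_values(yv, lab)
  structure(tibble(region_id = seq_along(vals) - 1L, value = vals),
            mu_ag = mean(vals), sigma2_ag = var_pop(vals),
            class = c("tbl_df", "tbl", "data.frame"))
}

# fast numeric dissolve (hot path)
dissolve_values <- function(yv, lab) {
  k <- max(lab) + 1L
  sums <- numeric(k)
  cnts <- tabulate(lab + 1L, nbins = k)
  sums <- as.numeric(rowsum(yv, lab, reorder = TRUE))
  sums / cnts
}

#' Batches of independent random aggregations
#'
#' Produces `r` contiguous `k`-partitions from sub-seeds derived
#' deterministically from a master seed, so a batch is reproducible without
#' reusing any seed.
#'
#' @inheritParams grow_regions
#' @param r number of aggregations (the experiments in this package use 30).
#' @return A list of `r` aggregation tibbles as returned by [grow_regions()].
#' @export
batch_aggregate <- function(w, k, r = 30, seed = NULL) {
  if (r < 1) abort("`r` must be a positive integer.")
  seed <- check_seed(seed)
  seeds <- derive_seeds(seed, r)
  lapply(seeds, function(s) grow_regions(w, k, s))
}
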