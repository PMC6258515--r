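#' Spatial contiguity weights
#'
#' A `spatial_weights` object stores a symmetric contiguity graph over `n`
#' areas. Area ids are 0-based and, for lattices, row-major: area
#' `r * ncols + c` sits in row `r`, column `c`. The object carries the
#' neighbour lists; the row-standardized weight matrix and the eigenvalues
#' needed by the SAR likelihood are derived on demand and cached.
#'
#' @param neighbors list of integer vectors, one per area, giving the 0-based
#'   ids of its neighbours.
#' @param lattice_dims optional `c(nrows, ncols)` recorded for lattice-born
#'   objects (used by plotting).
#' @return A `spatial_weights` object.
#' @export
spatial_weights <- function(neighbors, lattice_dims = NULL) {
  n <- length(neighbors)
  if (n < 2) abort("a weights object needs at least 2 areas.")
  nbr <- lapply(neighbors, function(v) sort(as.integer(v)) + 1L) # 1-based internal
  deg <- lengths(nbr)
  if (any(deg == 0L)) {
    abort(paste0("isolated area(s) with no neighbours: ",
                 paste(which(deg == 0L) - 1L, collapse = ", ")))
  }
  for (i in seq_len(n)) {
    v <- nbr[[i]]
    if (any(v < 1L | v > n)) abort("neighbour id out of range.")
    if (any(v == i)) abort("self-loops are not allowed.")
    if (anyDuplicated(v)) abort("duplicated neighbour listing.")
  }
  # symmetry
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      if (!i %in% nbr[[j]]) {
        abort(sprintf("asymmetric adjacency: %d lists %d but not vice versa.",
                      i - 1L, j - 1L))
      }
    }
  }
  w <- structure(
    list(n_areas = n, neighbors = nbr, lattice_dims = lattice_dims,
         cache = new.env(parent = emptyenv())),
    class = "spatial_weights")
  if (!w_is_connected(w)) {
    abort("the contiguity graph must be connected.")
  }
  w
}

#' Number of areas of a weights object
#' @param w a [spatial_weights] object.
#' @return integer count of areas.
#' @export
n_areas <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  w$n_areas
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<spatial_weights> %d areas, %d edges, mean degree %.2f\n",
              x$n_areas, sum(deg) / 2L, mean(deg)))
  if (!is.null(x$lattice_dims)) {
    cat(sprintf("  rook lattice %d x %d (row-major, 0-based ids)\n",
                x$lattice_dims[1], x$lattice_dims[2]))
  }
  invisible(x)
}

#' @export
as_tibble.spatial_weights <- function(x, ...) {
  from <- rep.int(seq_along(x$neighbors), lengths(x$neighbors)) - 1L
  to <- unlist(x$neighbors) - 1L
  tibble(from = from, to = to)[from < to, ]
}

# BFS connectivity from area 1
w_is_connected <- function(w) {
  n <- w$n_areas
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- w$neighbors[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Rook-contiguity regular lattice
#'
#' Builds the contiguity graph of an `nrows` x `ncols` grid in which two cells
#' are neighbours when they share an edge (rook rule). Interior cells have 4
#' neighbours, edges 3, corners 2; the statistic is designed for graphs whose
#' mean degree is close to 4, which these lattices satisfy.
#'
#' @param nrows,ncols positive integers; `nrows * ncols >= 2`.
#' @return A [spatial_weights] object with `nrows * ncols` areas, 0-based
#'   row-major ids.
#' @examples
#' w <- rook_lattice(5, 5)
#' n_areas(w)
#' @export
rook_lattice <- function(nrows, ncols) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 1L || ncols < 1L ||
      nrows * ncols < 2L) {
    abort("invalid lattice size: need nrows * ncols >= 2.")
  }
  id <- function(r, c) (r - 1L) * ncols + c - 1L
  nbr <- vector("list", nrows * ncols)
  for (r in seq_len(nrows)) {
    for (c in seq_len(ncols)) {
      v <- integer()
      if (r > 1L) v <- c(v, id(r - 1L, c))
      if (r < nrows) v <- c(v, id(r + 1L, c))
      if (c > 1L) v <- c(v, id(r, c - 1L))
      if (c < ncols) v <- c(v, id(r, c + 1L))
      nbr[[id(r, c) + 1L]] <- v
    }
  }
  spatial_weights(nbr, lattice_dims = c(nrows, ncols))
}

#' Row-standardized weight matrix
#'
#' Returns the sparse row-standardized contiguity matrix: `w[i, j] = 1 /
#' degree(i)` for neighbours `j`, so every row sums to one. Row
#' standardization keeps the SAR process `y = rho * W y + eps` stable for
#' `|rho| < 1` and is the convention used throughout the package (also by
#' Moran's I).
#'
#' @param w a [spatial_weights] object.
#' @return a `dgCMatrix` of dimension `n x n`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(w$cache$W)) return(w$cache$W)
  n <- w$n_areas
  deg <- lengths(w$neighbors)
  i <- rep.int(seq_len(n), deg)
  j <- unlist(w$neighbors)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
  w$cache$W <- W
  W
}

# eigenvalues of the row-standardized matrix, via the similar symmetric
# matrix D^{-1/2} A D^{-1/2}; real, in [-1, 1], cached per object
w_eigenvalues <- function(w) {
  if (!is.null(w$cache$ev)) return(w$cache$ev)
  n <- w$n_areas
  deg <- lengths(w$neighbors)
  i <- rep.int(seq_len(n), deg)
  j <- unlist(w$neighbors)
  S <- Matrix::sparseMatrix(i = i, j = j, x = 1 / sqrt(deg[i] * deg[j]),
                            dims = c(n, n))
  ev <- eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
  w$cache$ev <- ev
  ev
}

#' Read and write GAL contiguity files
#'
#' The GAL dialect used here is: a first line with the number of areas `n`,
#' then for each area one line `id k` (0-based id and neighbour count)
#' followed by one line with its `k` neighbour ids. `write_gal()` then
#' `read_gal()` is the identity on the edge set.
#'
#' A GAL file that lists `i -> j` without `j -> i` is rejected under
#' `strict = TRUE` (the default); with `strict = FALSE` the listing is
#' symmetrized and a warning is raised, so silent data errors cannot slip
#' through.
#'
#' @param path file path.
#' @param strict logical; reject asymmetric listings (default) or symmetrize
#'   with a warning.
#' @return `read_gal()` returns a [spatial_weights] object; `write_gal()`
#'   returns `path` invisibly.
#' @export
read_gal <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("GAL file not found: ", path))
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  n <- suppressWarnings(as.integer(strsplit(ln[[1]], "\\s+")[[1]][1]))
  if (is.na(n) || n < 1) abort("malformed GAL header.")
  nbr <- vector("list", n)
  pos <- 2L
  for (a in seq_len(n)) {
    if (pos + 1L > length(ln)) abort("truncated GAL file.")
    hd <- as.integer(strsplit(ln[[pos]], "\\s+")[[1]])
    if (length(hd) != 2L || anyNA(hd)) abort("malformed GAL area header line.")
    id <- hd[1]; kn <- hd[2]
    if (id < 0L || id >= n) abort("GAL area id out of range.")
    ids <- if (kn > 0L) as.integer(strsplit(ln[[pos + 1L]], "\\s+")[[1]]) else integer()
    if (length(ids) != kn || anyNA(ids)) abort("GAL neighbour line does not match its count.")
    nbr[[id + 1L]] <- ids
    pos <- pos + 2L
  }
  # symmetry policy
  asym <- list()
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      if (!(i - 1L) %in% nbr[[j + 1L]]) asym[[length(asym) + 1L]] <- c(i - 1L, j)
    }
  }
  if (length(asym)) {
    msg <- paste(vapply(asym, function(p) sprintf("%d->%d", p[1], p[2]), ""),
                 collapse = ", ")
    if (strict) abort(paste0("asymmetric GAL neighbour listing(s): ", msg))
    warn(paste0("symmetrized asymmetric GAL listing(s): ", msg))
    for (p in asym) nbr[[p[2] + 1L]] <- sort(c(nbr[[p[2] + 1L]], p[1]))
  }
  spatial_weights(nbr)
}

#' @param w a [spatial_weights] object to serialize.
#' @rdname read_gal
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  out <- character(1L + 2L * w$n_areas)
  out[1L] <- as.character(w$n_areas)
  for (a in seq_len(w$n_areas)) {
    nb <- w$neighbors[[a]] - 1L
    out[2L * a] <- paste(a - 1L, length(nb))
    out[2L * a + 1L] <- paste(nb, collapse = " ")
  }
  writeLines(out, path)
  invisible(path)
}
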