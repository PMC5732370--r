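#' Spatial weights objects
#'
#' A `spatial_weights` object holds the n x n weight matrix `L` of the
#' sPCA: row i contains weights reflecting the spatial proximity of every
#' unit to unit i. Weights are non-negative with zero diagonal; with the
#' default row standardisation every row sums to one, which makes the
#' per-axis identity eigenvalue = variance x Moran's I hold exactly.
#'
#' @name spatial_weights
NULL

new_spatial_weights <- function(L, style, graph_spec) {
  structure(list(L = L, style = style, graph_spec = graph_spec),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, style=%s, graph=%s\n",
              nrow(x$L), x$style,
              paste(deparse(x$graph_spec, nlines = 1L), collapse = "")))
  invisible(x)
}

as_coords <- function(xy) {
  if (is.data.frame(xy)) {
    if (ncol(xy) >= 3L && !is.numeric(xy[[1L]])) {
      m <- as.matrix(xy[, 2:3])
      rownames(m) <- as.character(xy[[1L]])
      xy <- m
    } else xy <- as.matrix(xy[, 1:2])
  }
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L) stop_validation("coordinates must be n x 2")
  if (any(!is.finite(xy))) stop_validation("coordinates must be finite")
  if (is.null(rownames(xy))) rownames(xy) <- paste0("unit_", seq_len(nrow(xy)))
  xy
}

#' Read coordinates or adjacency from CSV
#'
#' `read_coords` expects columns `unit,x,y`; `read_adjacency` a square
#' numeric matrix with unit ids as header and first column.
#'
#' @param path CSV file path.
#' @return `read_coords`: an n x 2 matrix with unit rownames;
#'   `read_adjacency`: a square numeric matrix.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop_validation("cannot read coordinates file: ", path)
  as_coords(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_coords
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop_validation("cannot read adjacency file: ", path)
  raw <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(raw)
}

row_standardise <- function(A) {
  rs <- rowSums(A)
  iso <- which(rs == 0)
  if (length(iso))
    stop_validation("isolated unit(s) with no neighbours: ",
                    paste(utils::head(rownames(A)[iso] %||% iso, 5L),
                          collapse = ", "))
  A / rs
}

#' Build a k-nearest-neighbour connection network
#'
#' Unit j is a neighbour of i iff j is among the k nearest Euclidean
#' neighbours of i; the graph is symmetrised by union and row-standardised.
#' Distance ties are broken deterministically in favour of the smaller
#' index.
#'
#' @param xy coordinates (n x 2 matrix with unit rownames, or a
#'   `unit,x,y` data frame).
#' @param k number of neighbours, `1 <= k <= n-1`.
#' @return A [spatial_weights] object (row-standardised).
#' @export
knn_graph <- function(xy, k) {
  xy <- as_coords(xy)
  n <- nrow(xy)
  if (k < 1L || k >= n)
    stop_validation("k must satisfy 1 <= k <= n-1")
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  A <- matrix(0, n, n, dimnames = list(rownames(xy), rownames(xy)))
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]  # order() is stable: ties -> smaller index
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                 # union symmetrisation
  new_spatial_weights(row_standardise(A), "row_standardised",
                      list(method = "knn", k = k))
}

#' Build a distance-band connection network
#'
#' Binary edge iff `d_min < dist <= d_max`; row-standardised. An isolated
#' unit is an error naming the unit (raise `d_max` to reconnect it).
#'
#' @inheritParams knn_graph
#' @param d_min,d_max distance band bounds, `0 <= d_min < d_max`.
#' @return A [spatial_weights] object (row-standardised).
#' @export
distance_graph <- function(xy, d_min = 0, d_max) {
  xy <- as_coords(xy)
  if (d_min < 0 || d_min >= d_max)
    stop_validation("need 0 <= d_min < d_max")
  D <- as.matrix(stats::dist(xy))
  A <- 1 * (D > d_min & D <= d_max)
  diag(A) <- 0
  new_spatial_weights(row_standardise(A), "row_standardised",
                      list(method = "distance", d_min = d_min, d_max = d_max))
}

#' Spatial weights from a user adjacency matrix
#'
#' @param A square non-negative matrix; a non-zero diagonal is forced to
#'   zero with a warning.
#' @param standardise row-standardise (default); otherwise weights are
#'   kept as given with style `"binary"`.
#' @param symmetrise replace A with max(A, t(A)) before use.
#' @return A [spatial_weights] object.
#' @export
weights_from_adjacency <- function(A, standardise = TRUE, symmetrise = FALSE) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_validation("adjacency must be square")
  if (any(A < 0)) stop_validation("adjacency weights must be non-negative")
  if (any(diag(A) != 0)) {
    warning("non-zero diagonal in adjacency; forcing to zero")
    diag(A) <- 0
  }
  if (symmetrise) A <- pmax(A, t(A))
  if (any(rowSums(A) == 0))
    stop_validation("isolated unit(s) with no neighbours: ",
                    paste(utils::head(which(rowSums(A) == 0), 5L),
                          collapse = ", "))
  if (standardise)
    new_spatial_weights(row_standardise(A), "row_standardised",
                        list(method = "adjacency", symmetrise = symmetrise))
  else
    new_spatial_weights(A, "binary",
                        list(method = "adjacency", symmetrise = symmetrise))
}

#' Jitter duplicated coordinates
#'
#' Every point sharing its exact coordinates with another point is
#' displaced by independent uniform noise in \[-magnitude, magnitude\] on
#' each axis (using the current RNG stream); all other points are
#' untouched.
#'
#' @inheritParams knn_graph
#' @param magnitude positive half-width of the uniform displacement.
#' @return Coordinate matrix of the same shape.
#' @export
jitter_duplicates <- function(xy, magnitude) {
  xy <- as_coords(xy)
  if (magnitude <= 0) stop_validation("magnitude must be > 0")
  key <- paste(xy[, 1L], xy[, 2L], sep = "\r")
  dup <- key %in% key[duplicated(key)]
  if (any(dup)) {
    k <- sum(dup)
    xy[dup, ] <- xy[dup, ] +
      matrix(stats::runif(2L * k, -magnitude, magnitude), k, 2L)
  }
  xy
}

# resolve a W argument: spatial_weights object or raw matrix used as L
weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) return(W$L)
  if (is.matrix(W) && nrow(W) == ncol(W)) return(W)
  stop_validation("W must be a spatial_weights object or a square matrix")
}

weights_style <- function(W) {
  if (inherits(W, "spatial_weights")) W$style else "custom"
}
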