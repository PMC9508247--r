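#' Construct an areal adjacency graph
#'
#' An areal graph is the spatial index set for lattice/areal data: an
#' undirected graph whose vertices are the areal units and whose edges join
#' adjacent units. It backs the CAR and Leroux precision matrices, which
#' require a connected graph (otherwise \code{D - rho * A} decomposes into
#' independent blocks and the dependence parameter loses its meaning), so
#' disconnected input is rejected.
#'
#' @param edges two-column integer matrix of undirected edges, 1-based
#'   vertex ids. Duplicate and reversed edges are collapsed; self loops are
#'   an error.
#' @param n number of vertices. Defaults to the largest id in \code{edges}.
#' @return An object of class \code{areal_graph} with components \code{n},
#'   \code{edges} (canonicalized, i < j), \code{degrees}, and \code{adjacency}
#'   (sparse symmetric 0/1 \code{\link[Matrix]{Matrix}}).
#' @examples
#' g <- areal_graph(rbind(c(1, 2), c(2, 3)))
#' g$degrees
#' @export
areal_graph <- function(edges, n = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) stop("areal graph needs at least one edge")
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 1L)) stop("vertex ids must be positive integers")
  if (any(edges[, 1L] == edges[, 2L])) stop("self loops are not allowed")
  if (is.null(n)) n <- max(edges)
  n <- as.integer(n)
  if (any(edges > n)) stop("edge refers to vertex id beyond 'n'")
  # canonical order i < j, drop duplicates
  ij <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  ij <- unique(ij)
  A <- Matrix::sparseMatrix(
    i = c(ij[, 1L], ij[, 2L]), j = c(ij[, 2L], ij[, 1L]),
    x = 1, dims = c(n, n)
  )
  A <- methods::as(A, "symmetricMatrix")
  degrees <- Matrix::rowSums(A)
  if (any(degrees == 0) || !graph_is_connected(ij, n)) {
    stop("areal graph must be connected")
  }
  structure(
    list(n = n, edges = ij, degrees = degrees, adjacency = A,
         cache = new.env(parent = emptyenv())),
    class = "areal_graph"
  )
}

# breadth-first search over the edge list
graph_is_connected <- function(ij, n) {
  adj <- split(c(ij[, 2L], ij[, 1L]), c(ij[, 1L], ij[, 2L]))
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[as.character(v)]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.areal_graph <- function(x, ...) {
  cat("Areal graph:", x$n, "vertices,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Rook-adjacency square lattice graph
#'
#' Builds the grid graph used for areal simulation scenarios: vertices are
#' lattice cells in row-major order from the lower-left corner, and two
#' cells are adjacent when they share an edge (rook moves, 4 neighbours).
#'
#' @param rows,cols lattice dimensions, both at least 2.
#' @return An \code{\link{areal_graph}} with \code{rows * cols} vertices.
#' @examples
#' g <- square_lattice(3, 3)
#' table(g$degrees)
#' @export
square_lattice <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 2L || cols < 2L) {
    stop("'rows' and 'cols' must both be at least 2")
  }
  idx <- function(r, c) (r - 1L) * cols + c
  horiz <- cbind(
    idx(rep(seq_len(rows), each = cols - 1L), rep(seq_len(cols - 1L), rows)),
    idx(rep(seq_len(rows), each = cols - 1L), rep(seq_len(cols - 1L), rows) + 1L)
  )
  vert <- cbind(
    idx(rep(seq_len(rows - 1L), each = cols), rep(seq_len(cols), rows - 1L)),
    idx(rep(seq_len(rows - 1L), each = cols) + 1L, rep(seq_len(cols), rows - 1L))
  )
  areal_graph(rbind(horiz, vert), n = rows * cols)
}

#' Construct a planar point set
#'
#' A point set is the spatial index set for continuous-domain (point-level)
#' data: planar coordinates plus the matrix of pairwise Euclidean
#' distances consumed by the correlation kernels. Coordinates must be in
#' the same length units as the kernel range parameters. Duplicate
#' locations are rejected because they make every kernel correlation
#' matrix singular.
#'
#' @param coords two-column numeric matrix of planar locations.
#' @return An object of class \code{point_set} with components \code{n},
#'   \code{coords}, and \code{dists}.
#' @export
point_set <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("'coords' must have two columns (x, y)")
  if (anyNA(coords) || any(!is.finite(coords))) stop("coordinates must be finite")
  d <- pairwise_distances(coords)
  structure(
    list(n = nrow(coords), coords = coords, dists = d),
    class = "point_set"
  )
}

#' @export
print.point_set <- function(x, ...) {
  cat("Point set:", x$n, "planar locations\n")
  invisible(x)
}

#' Regular grid of points in the unit square centered at the origin
#'
#' Point-level analogue of \code{\link{square_lattice}}: a \code{rows} by
#' \code{cols} grid of locations whose x and y coordinates each span
#' \code{[-0.5, 0.5]} inclusive. Points are ordered row-major from the
#' lower-left corner, matching the lattice vertex order, so the same grid
#' cell has the same index under both spatial domain notions.
#'
#' @inheritParams square_lattice
#' @return A \code{\link{point_set}} with \code{rows * cols} locations.
#' @export
unit_square_grid <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 2L || cols < 2L) {
    stop("'rows' and 'cols' must both be at least 2")
  }
  xs <- seq(-0.5, 0.5, length.out = cols)
  ys <- seq(-0.5, 0.5, length.out = rows)
  coords <- cbind(
    x = rep(xs, times = rows),
    y = rep(ys, each = cols)
  )
  point_set(coords)
}

#' Pairwise Euclidean distance matrix
#'
#' @param coords matrix of planar points, one row per point.
#' @return Symmetric zero-diagonal matrix of Euclidean distances.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 1L) return(matrix(0, 1L, 1L))
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate coordinates found; distance matrix would be degenerate")
  }
  d
}

#' Coordinates attached to the cells of a square lattice
#'
#' The simulation scenarios treat lattice cells both as graph vertices (for
#' the copula) and as locations in the unit square centered at the origin
#' (for the covariates). This helper returns those locations in the lattice
#' vertex order.
#'
#' @inheritParams square_lattice
#' @return Two-column matrix of (x, y) coordinates.
#' @export
lattice_coordinates <- function(rows, cols) {
  unit_square_grid(rows, cols)$coords
}
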