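#' Node-centered uniform 3D grid
#'
#' A regular grid is the geometric backbone of the solver: `n` nodes per
#' axis, uniform spacings `h` (metres) and the physical coordinate of the
#' first node (`origin`).  Node `(i, j, k)` (1-based) sits at
#' `origin + (i-1, j-1, k-1) * h`, an exact affine bijection in both
#' directions.  The linearization used throughout the package (and by the
#' assembled sparse operator) is R's native array order: x fastest, then
#' y, then z.
#'
#' @param n integer vector of length 3 (or a scalar, recycled): node
#'   counts per axis, each at least 3.
#' @param h numeric vector of length 3 (or a scalar): grid spacings in
#'   metres, strictly positive.
#' @param origin numeric length-3 vector: physical coordinate of node
#'   `(1, 1, 1)` in metres.
#' @return An object of class `"regular_grid"` with fields `n`, `h`,
#'   `origin`.
#' @seealso [make_cube_grid()] for the fictitious cubic domain used in the
#'   validation studies.
#' @export
regular_grid <- function(n, h, origin = c(0, 0, 0)) {
  n <- as.integer(rep_len(n, 3L))
  h <- as.numeric(rep_len(h, 3L))
  origin <- as.numeric(origin)
  if (anyNA(n) || any(n < 3L))
    stop("grid needs at least 3 nodes per axis", call. = FALSE)
  if (anyNA(h) || any(h <= 0))
    stop("grid spacings must be strictly positive", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("origin must be a finite length-3 vector", call. = FALSE)
  structure(list(n = n, h = h, origin = origin), class = "regular_grid")
}

#' Cubic fictitious computational domain
#'
#' Builds the cube-shaped embedding box used by the fictitious-domain
#' method: edge length `edge` centred on the coordinate origin, with `n`
#' nodes per axis, so the spacing is `edge / (n - 1)` and the outermost
#' node layers lie exactly on the box faces.
#'
#' @param edge edge length of the cube in metres (> 0).
#' @param n nodes per axis (>= 3).
#' @return A [regular_grid()].
#' @examples
#' g <- make_cube_grid(0.1, 128)   # h = 0.1/127 on every axis
#' @export
make_cube_grid <- function(edge, n) {
  if (!is.numeric(edge) || length(edge) != 1L || !is.finite(edge) || edge <= 0)
    stop("edge length must be a positive number", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("need at least 3 nodes per axis", call. = FALSE)
  h <- edge / (n - 1)
  regular_grid(n = c(n, n, n), h = c(h, h, h),
               origin = c(-edge / 2, -edge / 2, -edge / 2))
}

#' @export
print.regular_grid <- function(x, ...) {
  cat(sprintf("<regular_grid> %d x %d x %d nodes, h = (%g, %g, %g) m\n",
              x$n[1], x$n[2], x$n[3], x$h[1], x$h[2], x$h[3]))
  cat(sprintf("  origin (%g, %g, %g) m, extent (%g, %g, %g) m\n",
              x$origin[1], x$origin[2], x$origin[3],
              (x$n[1] - 1) * x$h[1], (x$n[2] - 1) * x$h[2],
              (x$n[3] - 1) * x$h[3]))
  invisible(x)
}

#' Map grid indices to physical coordinates
#'
#' @param grid a [regular_grid()].
#' @param ijk integer matrix with 3 columns (or length-3 vector) of
#'   1-based node indices.
#' @return Numeric matrix of physical coordinates (metres), one row per
#'   node.
#' @export
index_to_coord <- function(grid, ijk) {
  ijk <- rbind(ijk)
  if (ncol(ijk) != 3L) stop("ijk must have 3 columns", call. = FALSE)
  sweep(sweep(ijk - 1, 2L, grid$h, `*`), 2L, grid$origin, `+`)
}

#' Map physical coordinates to the nearest grid node
#'
#' The exact inverse of [index_to_coord()] on node coordinates; arbitrary
#' points snap to the nearest node.
#'
#' @inheritParams index_to_coord
#' @param xyz numeric matrix with 3 columns (or length-3 vector) of
#'   physical coordinates in metres.
#' @return Integer matrix of 1-based node indices.
#' @export
coord_to_index <- function(grid, xyz) {
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns", call. = FALSE)
  ijk <- round(sweep(sweep(xyz, 2L, grid$origin, `-`), 2L, grid$h, `/`)) + 1
  storage.mode(ijk) <- "integer"
  ijk
}

#' Per-axis node coordinate vectors
#'
#' @inheritParams index_to_coord
#' @return A list with components `x`, `y`, `z` holding the node
#'   coordinates along each axis.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$n[1]) - 1) * grid$h[1],
       y = grid$origin[2] + (seq_len(grid$n[2]) - 1) * grid$h[2],
       z = grid$origin[3] + (seq_len(grid$n[3]) - 1) * grid$h[3])
}

# 1-based linear index of node (i,j,k); x fastest, matching R array order.
grid_linear_index <- function(grid, ijk) {
  ijk <- rbind(ijk)
  ijk[, 1] + (ijk[, 2] - 1L) * grid$n[1] +
    (ijk[, 3] - 1L) * grid$n[1] * grid$n[2]
}

# Logical 3D array marking the outer-boundary (Dirichlet) nodes.
boundary_mask <- function(grid) {
  n <- grid$n
  m <- array(FALSE, n)
  m[c(1, n[1]), , ] <- TRUE
  m[, c(1, n[2]), ] <- TRUE
  m[, , c(1, n[3])] <- TRUE
  m
}

same_grid <- function(a, b) {
  identical(a$n, b$n) && isTRUE(all.equal(a$h, b$h)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
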