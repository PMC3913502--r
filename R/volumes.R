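#' Scalar volume on a regular grid
#'
#' One real value per grid node (a potential, a source density, ...),
#' stored as a 3D array whose dimensions match the grid node counts.
#'
#' @param grid a [regular_grid()].
#' @param values numeric 3D array of dimension `grid$n`, or a scalar which
#'   is recycled.
#' @return An object of class `"scalar_volume"` with fields `grid`,
#'   `values`.
#' @export
scalar_volume <- function(grid, values = 0) {
  stopifnot(inherits(grid, "regular_grid"))
  if (length(values) == 1L) values <- array(as.numeric(values), grid$n)
  if (!is.array(values) || !identical(dim(values), as.integer(grid$n)))
    stop("values must be an array of dimension matching the grid",
         call. = FALSE)
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %d x %d x %d, range [%g, %g]\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Symmetric conductivity tensor field
#'
#' Stores one symmetric 3x3 conductivity tensor (S/m) per grid node as six
#' component volumes; symmetry is structural.  Every tensor must be
#' positive definite -- air cladding in the fictitious-domain method uses a
#' small positive conductivity, never zero.
#'
#' @param grid a [regular_grid()].
#' @param xx,yy,zz,xy,xz,yz numeric 3D arrays (or scalars, recycled) with
#'   the tensor components in S/m.
#' @param check if `TRUE` (default) verify positive definiteness at every
#'   node at construction.
#' @return An object of class `"tensor_field"`.
#' @seealso [check_positive_definite()]
#' @export
tensor_field <- function(grid, xx, yy, zz, xy = 0, xz = 0, yz = 0,
                         check = TRUE) {
  stopifnot(inherits(grid, "regular_grid"))
  expand <- function(v) {
    if (length(v) == 1L) v <- array(as.numeric(v), grid$n)
    if (!is.array(v) || !identical(dim(v), as.integer(grid$n)))
      stop("tensor component dimensions must match the grid", call. = FALSE)
    v
  }
  obj <- structure(list(grid = grid, xx = expand(xx), yy = expand(yy),
                        zz = expand(zz), xy = expand(xy), xz = expand(xz),
                        yz = expand(yz)),
                   class = "tensor_field")
  if (check) check_positive_definite(obj)
  obj
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d x %d nodes\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3]))
  cat(sprintf("  diag ranges: xx [%g, %g], yy [%g, %g], zz [%g, %g] S/m\n",
              min(x$xx), max(x$xx), min(x$yy), max(x$yy),
              min(x$zz), max(x$zz)))
  invisible(x)
}

#' Verify positive definiteness of a tensor field
#'
#' A symmetric 3x3 matrix is positive definite iff its three leading
#' principal minors are positive (Sylvester's criterion) -- equivalent to
#' all eigenvalues being positive, and vectorizable over the whole volume.
#'
#' @param sigma a [tensor_field()].
#' @return Invisibly `TRUE`; throws an error naming the first offending
#'   node otherwise.
#' @export
check_positive_definite <- function(sigma) {
  stopifnot(inherits(sigma, "tensor_field"))
  m1 <- sigma$xx
  m2 <- sigma$xx * sigma$yy - sigma$xy^2
  m3 <- sigma$xx * (sigma$yy * sigma$zz - sigma$yz^2) -
    sigma$xy * (sigma$xy * sigma$zz - sigma$yz * sigma$xz) +
    sigma$xz * (sigma$xy * sigma$yz - sigma$yy * sigma$xz)
  bad <- m1 <= 0 | m2 <= 0 | m3 <= 0
  if (any(bad)) {
    ijk <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "conductivity tensor is not positive definite at node (%d, %d, %d)",
      ijk[1], ijk[2], ijk[3]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract the 3x3 tensor at one node
#'
#' @param sigma a [tensor_field()].
#' @param ijk length-3 integer vector of 1-based node indices.
#' @return A symmetric 3x3 numeric matrix (S/m).
#' @export
tensor_at <- function(sigma, ijk) {
  i <- ijk[1]; j <- ijk[2]; k <- ijk[3]
  matrix(c(sigma$xx[i, j, k], sigma$xy[i, j, k], sigma$xz[i, j, k],
           sigma$xy[i, j, k], sigma$yy[i, j, k], sigma$yz[i, j, k],
           sigma$xz[i, j, k], sigma$yz[i, j, k], sigma$zz[i, j, k]),
         3, 3)
}

#' Isotropic tensor field from a scalar conductivity volume
#'
#' @param grid a [regular_grid()].
#' @param values scalar or 3D array of conductivities (S/m).
#' @return A diagonal [tensor_field()] with `xx = yy = zz = values`.
#' @export
isotropic_tensor_field <- function(grid, values) {
  if (length(values) == 1L) values <- array(as.numeric(values), grid$n)
  tensor_field(grid, xx = values, yy = values, zz = values, check = FALSE)
}
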