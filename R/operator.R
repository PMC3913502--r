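#' Assemble the 19-diagonal finite-difference operator
#'
#' Discretizes `nabla . (sigma nabla u)` on the grid: conservative
#' three-point second-derivative terms per axis plus the selected
#' mixed-derivative scheme for the six cross terms.  Interior rows have at
#' most 19 nonzeros; the outer-boundary nodes carry homogeneous Dirichlet
#' identity rows.  The sign convention is negative definite: for unit
#' isotropic conductivity the interior rows are the 7-point Laplacian with
#' `+1/h^2` neighbours and `-6/h^2` centre.  Rows are kept in physical
#' units (no `h^2` pre-scaling) so the Fourier preconditioner's
#' closed-form eigenvalues apply unchanged.
#'
#' @param sigma a positive-definite [tensor_field()].
#' @param grid the grid; defaults to the field's grid and must match it.
#' @param scheme one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"` selecting the
#'   mixed-derivative approximation (see the methods vignette).
#' @param b_split for scheme B only: `"printed"` uses the splitting
#'   `s +- |s|`; `"halved"` the conventional `(s +- |s|)/2` variant.
#' @return An object of class `"discrete_operator"`: fields `A` (a
#'   `dgCMatrix` of dimension `prod(grid$n)` squared), `scheme`, `grid`,
#'   `sigma`, `b_split`.
#' @export
assemble_operator <- function(sigma, grid = sigma$grid, scheme = "A",
                              b_split = c("printed", "halved")) {
  stopifnot(inherits(sigma, "tensor_field"))
  b_split <- match.arg(b_split)
  if (!same_grid(grid, sigma$grid))
    stop("grid does not match the tensor field's grid", call. = FALSE)
  sc <- stencil_coefficients(sigma, grid, scheme, b_split)
  n <- grid$n
  N <- prod(n)
  idx <- array(seq_len(N), n)
  interior <- as.vector(idx[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)])
  off_lin <- sc$offsets[, 1] + sc$offsets[, 2] * n[1] +
    sc$offsets[, 3] * n[1] * n[2]
  # Build the CSC structure of t(A) directly -- the row structure of A is
  # known in closed form (19 offsets, sorted, per interior row; identity
  # on boundary rows), which avoids the expensive generic triplet sort --
  # then transpose once at C level.
  ord <- order(off_lin)
  nper <- rep.int(1L, N)
  nper[interior] <- nrow(sc$offsets)
  ptr <- c(0L, cumsum(nper))
  nnz <- ptr[N + 1L]
  jj <- integer(nnz)
  xxv <- numeric(nnz)
  pos0 <- ptr[interior]          # 0-based start of each interior row
  for (s in seq_along(ord)) {
    r <- ord[s]
    at <- pos0 + s
    jj[at] <- interior + off_lin[r]
    xxv[at] <- sc$coef[[r]][interior]
  }
  bnd <- which(boundary_mask(grid))
  jj[ptr[bnd] + 1L] <- bnd
  xxv[ptr[bnd] + 1L] <- 1
  At <- methods::new("dgCMatrix", i = jj - 1L, p = ptr, x = xxv,
                     Dim = c(as.integer(N), as.integer(N)))
  At <- Matrix::drop0(At)
  A <- Matrix::t(At)
  structure(list(A = A, scheme = sc$scheme, grid = grid, sigma = sigma,
                 b_split = b_split),
            class = "discrete_operator")
}

#' @export
print.discrete_operator <- function(x, ...) {
  cat(sprintf("<discrete_operator> scheme %s, %d x %d, %d nonzeros\n",
              x$scheme, nrow(x$A), ncol(x$A), Matrix::nnzero(x$A)))
  invisible(x)
}

#' Apply the discrete operator to a potential volume
#'
#' Either through the assembled sparse matrix or matrix-free by summing
#' shifted coefficient arrays; the two paths agree to round-off.
#'
#' @param op a [assemble_operator()] result.
#' @param u a [scalar_volume()], 3D array, or plain vector of length
#'   `prod(grid$n)`.
#' @param method `"sparse"` (default) or `"matrix_free"`.
#' @return A [scalar_volume()] holding `A u` (boundary rows are the
#'   Dirichlet identity, so boundary values pass through).
#' @export
apply_operator <- function(op, u, method = c("sparse", "matrix_free")) {
  method <- match.arg(method)
  grid <- op$grid
  uv <- if (inherits(u, "scalar_volume")) u$values else u
  if (length(uv) != prod(grid$n))
    stop("shape mismatch between operator and potential", call. = FALSE)
  if (method == "sparse") {
    y <- as.numeric(op$A %*% as.numeric(uv))
  } else {
    ua <- array(as.numeric(uv), grid$n)
    sc <- stencil_coefficients(op$sigma, grid, op$scheme, op$b_split)
    y <- array(0, grid$n)
    for (r in seq_len(nrow(sc$offsets)))
      y <- y + sc$coef[[r]] * shift_array(ua, sc$offsets[r, ])
    bm <- boundary_mask(grid)
    y[bm] <- ua[bm]
  }
  scalar_volume(grid, array(y, grid$n))
}

#' Diagonal of the assembled operator
#'
#' @param op a [assemble_operator()] result.
#' @return Numeric vector of length `prod(grid$n)`.
#' @export
operator_diagonal <- function(op) Matrix::diag(op$A)

#' Export the operator in MatrixMarket coordinate format
#'
#' Writes the sparse matrix as plain-text coordinate triplets for
#' cross-checking in external tools, plus a small JSON-like header file
#' with the grid metadata.
#'
#' @param op a [assemble_operator()] result.
#' @param path output file path (`.mtx`).
#' @return Invisibly, `path`.
#' @export
write_operator_mm <- function(op, path) {
  Matrix::writeMM(op$A, path)
  meta <- sprintf(
    '{"scheme": "%s", "n": [%s], "h": [%s], "origin": [%s]}',
    op$scheme, paste(op$grid$n, collapse = ", "),
    paste(op$grid$h, collapse = ", "),
    paste(op$grid$origin, collapse = ", "))
  writeLines(meta, paste0(path, ".json"))
  invisible(path)
}

#' Deposit a dipolar source on the grid
#'
#' Realizes a current source-sink pair as two delta-like monopoles: the
#' endpoints `position +- orientation * separation / 2` snap to their
#' nearest grid nodes, which receive source densities `+- current / (hx hy
#' hz)` so that the volume integral of the field equals the injected
#' current exactly and the total sums to zero.
#'
#' @param grid a [regular_grid()].
#' @param position dipole centre (metres, length-3).
#' @param orientation dipole axis (need not be normalized).
#' @param separation distance between the monopoles (metres).
#' @param current injected current (amperes).
#' @return An object of class `"source_field"`: fields `f` (a
#'   [scalar_volume()] of source densities), `monopoles` (a data frame of
#'   node indices and currents).
#' @export
build_dipole_rhs <- function(grid, position, orientation, separation,
                             current = 1) {
  stopifnot(inherits(grid, "regular_grid"))
  orientation <- as.numeric(orientation)
  nrm <- sqrt(sum(orientation^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("orientation must be a nonzero vector", call. = FALSE)
  orientation <- orientation / nrm
  ends <- rbind(position + orientation * separation / 2,
                position - orientation * separation / 2)
  ax <- grid_axes(grid)
  lo <- c(ax$x[1], ax$y[1], ax$z[1])
  hi <- c(ax$x[grid$n[1]], ax$y[grid$n[2]], ax$z[grid$n[3]])
  if (any(t(ends) < lo - 1e-12) || any(t(ends) > hi + 1e-12))
    stop("dipole endpoint falls outside the grid", call. = FALSE)
  ijk <- coord_to_index(grid, ends)
  if (all(ijk[1, ] == ijk[2, ]))
    stop("degenerate dipole: both endpoints snap to the same node",
         call. = FALSE)
  dens <- current / prod(grid$h)
  f <- array(0, grid$n)
  f[rbind(ijk[1, ])] <- f[rbind(ijk[1, ])] + dens
  f[rbind(ijk[2, ])] <- f[rbind(ijk[2, ])] - dens
  structure(list(
    f = scalar_volume(grid, f),
    monopoles = data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                           current = c(current, -current))),
    class = "source_field")
}

#' @export
print.source_field <- function(x, ...) {
  cat(sprintf("<source_field> %d monopoles, net current %g A\n",
              nrow(x$monopoles), sum(x$monopoles$current)))
  invisible(x)
}

# Coerce a right-hand side to a plain vector with Dirichlet-consistent
# (zero) boundary entries.
rhs_vector <- function(rhs, grid) {
  v <- if (inherits(rhs, "source_field")) rhs$f$values
  else if (inherits(rhs, "scalar_volume")) rhs$values
  else rhs
  if (length(v) != prod(grid$n))
    stop("right-hand side does not match the grid", call. = FALSE)
  v <- array(as.numeric(v), grid$n)
  v[boundary_mask(grid)] <- 0
  as.numeric(v)
}
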