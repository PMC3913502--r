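# Preconditioners: opaque objects with a linear `apply` contract
# z = P^{-1} r (and, for the one nonsymmetric composition, an `apply_t`
# contract z = P^{-T} r used for the BiCG shadow recurrence).

new_preconditioner <- function(kind, apply, apply_t = NULL, ...) {
  structure(list(kind = kind, apply = apply,
                 apply_t = if (is.null(apply_t)) apply else apply_t, ...),
            class = "preconditioner")
}

#' Apply a preconditioner to a residual-shaped vector
#'
#' @param P a preconditioner from [jacobi_preconditioner()],
#'   [fourier_preconditioner()], [fourier_jacobi_preconditioner()] or
#'   [identity_preconditioner()].
#' @param r numeric vector (or [scalar_volume()] / array) shaped like a
#'   residual.
#' @param transpose apply `P^{-T}` instead of `P^{-1}` (identical for the
#'   symmetric preconditioners).
#' @return Numeric vector `z ~ P^{-1} r`.
#' @export
precond_apply <- function(P, r, transpose = FALSE) {
  stopifnot(inherits(P, "preconditioner"))
  v <- if (inherits(r, "scalar_volume")) as.numeric(r$values) else as.numeric(r)
  if (transpose) P$apply_t(v) else P$apply(v)
}

#' @export
print.preconditioner <- function(x, ...) {
  cat(sprintf("<preconditioner> %s\n", x$kind))
  invisible(x)
}

#' Identity (no) preconditioner
#'
#' @return A preconditioner whose apply is the identity.
#' @export
identity_preconditioner <- function() {
  new_preconditioner("none", function(r) r)
}

#' Jacobi (diagonal) preconditioner
#'
#' `apply(r) = r / diag(A)` elementwise.  The simplest preconditioner: it
#' helps with strongly inhomogeneous coefficients (the fictitious-domain
#' air cladding) but does not remove the growth of iteration counts with
#' grid resolution.
#'
#' @param op a [assemble_operator()] result.
#' @return A `"preconditioner"` object.
#' @export
jacobi_preconditioner <- function(op) {
  d <- operator_diagonal(op)
  if (any(d == 0)) {
    node <- which(d == 0)[1]
    stop(sprintf("singular Jacobi preconditioner: zero diagonal at node %d",
                 node), call. = FALSE)
  }
  new_preconditioner("jacobi", function(r) r / d, diagonal = d)
}

#' Fourier (sine-transform) preconditioner
#'
#' Inverts the constant-coefficient 7-point Dirichlet Laplacian `L0`
#' (coefficient `sigma0`, same negative-definite sign convention as the
#' assembled operator) exactly: forward 3D type-I sine transform of the
#' interior block, division by the closed-form eigenvalues
#' `-sigma0 * sum_axes (4/h^2) sin^2(pi m / (2 (n - 1)))` over interior
#' modes `m = 1 .. n-2`, inverse transform.  Boundary (Dirichlet identity)
#' entries pass through unchanged.  On the homogeneous isotropic problem
#' with matching coefficient the preconditioner equals the operator and
#' Krylov iteration converges in one step.
#'
#' @param grid a [regular_grid()] (uniform by construction).
#' @param coefficient the scalar conductivity `sigma0` (S/m), > 0.
#' @return A `"preconditioner"` object.
#' @seealso [fourier_coefficient()] for the automatic choice of
#'   `sigma0` from a tensor field.
#' @export
fourier_preconditioner <- function(grid, coefficient = 1) {
  stopifnot(inherits(grid, "regular_grid"))
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient) || coefficient <= 0)
    stop("Fourier coefficient must be a positive number", call. = FALSE)
  n <- grid$n; h <- grid$h
  m <- n - 2L
  S <- lapply(1:3, function(ax) dst_matrix(m[ax]))
  lam_ax <- lapply(1:3, function(ax)
    (4 / h[ax]^2) * sin(pi * seq_len(m[ax]) / (2 * (n[ax] - 1)))^2)
  lambda <- coefficient *
    (outer(outer(lam_ax[[1]], lam_ax[[2]], `+`), lam_ax[[3]], `+`))
  ix <- 2:(n[1] - 1); iy <- 2:(n[2] - 1); iz <- 2:(n[3] - 1)
  apply_fun <- function(r) {
    ra <- array(r, n)
    z <- ra
    rint <- ra[ix, iy, iz]
    zint <- -idst3(dst3(rint, S) / lambda, S)
    z[ix, iy, iz] <- zint
    as.numeric(z)
  }
  new_preconditioner("fourier", apply_fun, coefficient = coefficient,
                     lambda = lambda, grid = grid)
}

#' Automatic Fourier coefficient from a tensor field
#'
#' Mean of the three diagonal tensor components over the physical
#' (non-air) region, where "air" is any node whose mean diagonal
#' conductivity falls below `air_threshold`.
#'
#' @param sigma a [tensor_field()].
#' @param air_threshold conductivity (S/m) below which a node counts as
#'   air cladding.
#' @return A positive scalar (S/m).
#' @export
fourier_coefficient <- function(sigma, air_threshold = 1e-8) {
  tr3 <- (sigma$xx + sigma$yy + sigma$zz) / 3
  phys <- tr3 > air_threshold
  if (!any(phys)) return(mean(tr3))
  mean(tr3[phys])
}

#' Combined Fourier-Jacobi preconditioner
#'
#' The workhorse preconditioner: combines the diagonal of the assembled
#' operator with the unit-coefficient Dirichlet Laplacian solve, making
#' Krylov iteration counts independent of both grid resolution and the
#' conductivity heterogeneity ratio.  Two compositions are provided (the
#' combination formula is an interpretation; see the methods vignette):
#'
#' * `"sequential"` (default): Jacobi then Fourier, `apply(r) = L0^{-1}
#'   (r / D)` with `D = |diag(A)|`, plus the matching transpose apply
#'   `r / D` after the Fourier solve for the BiCG shadow recurrence.
#'   This composition reproduces the reference flat iteration counts on
#'   the layered sphere (see the methods vignette measurements).
#' * `"symmetric"`: `apply(r) = D^{-1/2} L0^{-1} D^{-1/2} r`.  Preserves
#'   symmetry of symmetric operators and collapses to a scalar multiple
#'   of the pure Fourier preconditioner in the homogeneous limit, but
#'   converges markedly slower on strongly layered models.
#'
#' The absolute value on the diagonal guards against a flipped sign
#' convention of `A`.
#'
#' @param op a [assemble_operator()] result.
#' @param grid the operator grid (defaulted).
#' @param composition `"symmetric"` or `"sequential"`.
#' @return A `"preconditioner"` object.
#' @export
fourier_jacobi_preconditioner <- function(op, grid = op$grid,
                                          composition = c("sequential",
                                                          "symmetric")) {
  composition <- match.arg(composition)
  d <- abs(operator_diagonal(op))
  if (any(d == 0)) {
    node <- which(d == 0)[1]
    stop(sprintf(
      "singular Fourier-Jacobi preconditioner: zero diagonal at node %d",
      node), call. = FALSE)
  }
  FP <- fourier_preconditioner(grid, coefficient = 1)
  if (composition == "symmetric") {
    dis <- 1 / sqrt(d)
    new_preconditioner("fourier_jacobi",
                       function(r) dis * FP$apply(dis * r),
                       composition = composition, diagonal = d)
  } else {
    new_preconditioner("fourier_jacobi",
                       apply = function(r) FP$apply(r / d),
                       apply_t = function(r) FP$apply(r) / d,
                       composition = composition, diagonal = d)
  }
}

#' Build a preconditioner by name
#'
#' @param kind one of `"none"`, `"jacobi"`, `"fourier"`,
#'   `"fourier_jacobi"`.
#' @param op the assembled operator (required except for `"none"`).
#' @param fourier_coefficient `"auto"` (mean physical conductivity) or a
#'   positive number; used by `"fourier"` only.
#' @param fj_composition passed to [fourier_jacobi_preconditioner()].
#' @return A `"preconditioner"` object.
#' @export
make_preconditioner <- function(kind = c("none", "jacobi", "fourier",
                                         "fourier_jacobi"),
                                op = NULL, fourier_coefficient = "auto",
                                fj_composition = "sequential") {
  kind <- match.arg(kind)
  if (kind == "none") return(identity_preconditioner())
  if (is.null(op)) stop("operator required for this preconditioner",
                        call. = FALSE)
  switch(kind,
         jacobi = jacobi_preconditioner(op),
         fourier = {
           coef <- if (identical(fourier_coefficient, "auto"))
             fourier_coefficient(op$sigma) else as.numeric(fourier_coefficient)
           fourier_preconditioner(op$grid, coef)
         },
         fourier_jacobi = fourier_jacobi_preconditioner(
           op, composition = fj_composition))
}
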