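test_that("DST round-trip is exact to round-off", {
  set.seed(4)
  S <- lapply(c(5L, 7L, 6L), eitfdm:::dst_matrix)
  x <- array(rnorm(5 * 7 * 6), c(5, 7, 6))
  y <- eitfdm:::idst3(eitfdm:::dst3(x, S), S)
  expect_lt(max(abs(y - x)) / max(abs(x)), 1e-12)
})

test_that("Fourier preconditioner inverts single sine modes by the closed-form eigenvalue", {
  g <- make_cube_grid(0.1, 10)
  n <- g$n[1]; m <- n - 2L; h <- g$h[1]
  FP <- fourier_preconditioner(g, coefficient = 2)
  mode <- c(2L, 3L, 1L)
  ax <- seq_len(m)
  r <- array(0, g$n)
  r[2:(n - 1), 2:(n - 1), 2:(n - 1)] <-
    outer(outer(sin(pi * mode[1] * ax / (m + 1)),
                sin(pi * mode[2] * ax / (m + 1))),
          sin(pi * mode[3] * ax / (m + 1)))
  lam <- 2 * sum((4 / h^2) * sin(pi * mode / (2 * (n - 1)))^2)
  z <- precond_apply(FP, scalar_volume(g, r))
  # negative-definite convention: apply(r) = -r / lambda
  expect_lt(max(abs(z + as.numeric(r) / lam)) / max(abs(r) / lam), 1e-12)
})

test_that("Fourier apply equals a direct sparse solve of L0", {
  g <- make_cube_grid(0.1, 8)
  L0 <- assemble_operator(isotropic_tensor_field(g, 1.3), scheme = "A")$A
  set.seed(6)
  r <- eitfdm:::rhs_vector(array(rnorm(prod(g$n)), g$n), g)
  z <- precond_apply(fourier_preconditioner(g, 1.3), r)
  zd <- as.numeric(Matrix::solve(L0, r))
  expect_lt(max(abs(z - zd)) / max(abs(zd)), 1e-10)
  # and apply(L0 x) = x for interior-supported x
  x <- eitfdm:::rhs_vector(array(rnorm(prod(g$n)), g$n), g)
  expect_lt(max(abs(precond_apply(fourier_preconditioner(g, 1.3),
                                  as.numeric(L0 %*% x)) - x)), 1e-10)
})

test_that("Jacobi preconditioner is the elementwise diagonal solve", {
  g <- make_cube_grid(0.1, 8)
  op <- assemble_operator(build_smooth_probe(g)$sigma, scheme = "A")
  P <- jacobi_preconditioner(op)
  d <- operator_diagonal(op)
  expect_equal(precond_apply(P, d), rep(1, length(d)))
  set.seed(8)
  r <- rnorm(length(d))
  zd <- as.numeric(Matrix::solve(Matrix::Diagonal(x = d), r))
  expect_lt(max(abs(precond_apply(P, r) - zd)) / max(abs(zd)), 1e-14)
})

test_that("preconditioner applies are linear and vanish at zero", {
  g <- make_cube_grid(0.1, 8)
  op <- assemble_operator(build_smooth_probe(g)$sigma, scheme = "E")
  set.seed(10)
  N <- prod(g$n)
  for (kind in c("jacobi", "fourier", "fourier_jacobi")) {
    P <- make_preconditioner(kind, op)
    expect_equal(precond_apply(P, numeric(N)), numeric(N))
    r1 <- rnorm(N); r2 <- rnorm(N)
    lhs <- precond_apply(P, 2 * r1 - 0.5 * r2)
    rhs <- 2 * precond_apply(P, r1) - 0.5 * precond_apply(P, r2)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-12)
  }
})

test_that("Fourier-Jacobi reduces to a scalar multiple of Fourier in the homogeneous limit", {
  g <- make_cube_grid(0.1, 9)
  sig0 <- 2.5
  op <- assemble_operator(isotropic_tensor_field(g, sig0), scheme = "A")
  FP <- fourier_preconditioner(g, 1)
  set.seed(12)
  r <- eitfdm:::rhs_vector(array(rnorm(prod(g$n)), g$n), g)
  for (comp in c("sequential", "symmetric")) {
    FJ <- fourier_jacobi_preconditioner(op, composition = comp)
    zf <- precond_apply(FP, r)
    zj <- precond_apply(FJ, r)
    ratio <- zj[zf != 0] / zf[zf != 0]
    expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-10)
  }
  # Krylov with FJ on the homogeneous problem converges immediately
  res <- bicg_solve(op, build_dipole_rhs(g, c(0, 0, 0), c(1, 0, 0),
                                         2 * g$h[1]),
                    fourier_jacobi_preconditioner(op),
                    solver_config(tolerance = 1e-8))
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
})

test_that("FJ preconditioning beats no preconditioning on the probe", {
  g <- make_cube_grid(0.1, 32)
  pr <- build_smooth_probe(g)
  op <- assemble_operator(pr$sigma, scheme = "A")
  cfg <- solver_config(tolerance = 1e-5, max_iterations = 500L)
  fj <- bicg_solve(op, pr$f, fourier_jacobi_preconditioner(op), cfg)
  no <- bicg_solve(op, pr$f, identity_preconditioner(), cfg)
  expect_true(fj$converged)
  expect_lte(fj$iterations, 15L)
  expect_gte(no$iterations, 40L)
})

test_that("singular diagonals are reported", {
  g <- make_cube_grid(1, 5)
  op <- assemble_operator(random_pd_field(g, seed = 2), scheme = "A")
  op$A[2, 2] <- 0
  expect_error(jacobi_preconditioner(op), "node 2")
  expect_error(fourier_jacobi_preconditioner(op), "node 2")
  expect_error(fourier_preconditioner(g, -1), "positive")
})
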