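test_that("scheme B splitting follows the printed formula", {
  expect_equal(scheme_b_split(2), list(plus = 4, minus = 0))
  expect_equal(scheme_b_split(-2), list(plus = 0, minus = -4))
  expect_equal(scheme_b_split(0), list(plus = 0, minus = 0))
  s <- c(-3, -0.5, 0, 0.2, 7)
  sp <- scheme_b_split(s)
  expect_true(all(sp$plus >= 0) && all(sp$minus <= 0))
  expect_equal(sp$plus + sp$minus, 2 * s)
  sph <- scheme_b_split(s, halved = TRUE)
  expect_equal(sph$plus + sph$minus, s)
})

test_that("identity conductivity gives the 7-point Laplacian", {
  g <- make_cube_grid(2, 7)
  h2 <- g$h[1]^2
  for (scheme in c("A", "B", "C", "D", "E")) {
    op <- assemble_operator(isotropic_tensor_field(g, 1), scheme = scheme)
    p <- eitfdm:::grid_linear_index(g, c(4, 4, 4))
    row <- op$A[p, ]
    expect_equal(row[p] * h2, -6, tolerance = 1e-12)
    nbr <- eitfdm:::grid_linear_index(
      g, rbind(c(5, 4, 4), c(3, 4, 4), c(4, 5, 4),
               c(4, 3, 4), c(4, 4, 5), c(4, 4, 3)))
    expect_equal(as.numeric(row[nbr]) * h2, rep(1, 6), tolerance = 1e-12)
    expect_equal(sum(row != 0), 7L)
  }
})

test_that("schemes A, C, D, E assemble identical matrices for a constant full tensor", {
  g <- make_cube_grid(2, 7)
  sig <- tensor_field(g, xx = 1, yy = 1, zz = 1, xy = 0.3, xz = 0.3,
                      yz = 0.3)
  mats <- lapply(c("A", "C", "D", "E"),
                 function(s) assemble_operator(sig, scheme = s)$A)
  for (k in 2:4)
    expect_lt(max(abs(mats[[1]] - mats[[k]])), 1e-14)
  # B differs for one-sign off-diagonals, but summing its split halves
  # (replacing s+ and s- each by s) reproduces the common matrix: the two
  # pairings average to the four-point scheme
  expect_gt(max(abs(mats[[1]] -
                      assemble_operator(sig, scheme = "B")$A)), 1e-3)
})

test_that("every scheme annihilates constants and has zero interior row sums", {
  g <- make_cube_grid(1, 8)
  sig <- random_pd_field(g, seed = 3)
  ones <- rep(1, prod(g$n))
  bm <- as.vector(eitfdm:::boundary_mask(g))
  scale <- 1 / g$h[1]^2
  for (scheme in c("A", "B", "C", "D", "E")) {
    op <- assemble_operator(sig, scheme = scheme)
    v <- as.numeric(op$A %*% ones)
    expect_lt(max(abs(v[!bm])) / scale, 1e-13)
    # boundary rows are the Dirichlet identity
    expect_equal(v[bm], rep(1, sum(bm)))
    # interior rows have at most 19 nonzeros
    nnz_per_row <- tabulate(op$A@i + 1L, nbins = nrow(op$A))
    expect_lte(max(nnz_per_row), 19L)
  }
})

test_that("assembled matvec matches the independent stencil-by-stencil oracle", {
  g <- make_cube_grid(0.1, 8)
  pr <- build_smooth_probe(g)
  set.seed(11)
  u <- scalar_volume(g, array(rnorm(prod(g$n)), g$n))
  for (scheme in c("A", "B", "C", "D", "E")) {
    op <- assemble_operator(pr$sigma, scheme = scheme)
    got <- apply_operator(op, u)$values
    want <- slow_stencil_apply(pr$sigma, g, scheme, u)
    expect_equal(got, want, tolerance = 1e-11,
                 label = sprintf("scheme %s matvec", scheme))
  }
  # and on a random heterogeneous field with sign-changing off-diagonals
  sig <- random_pd_field(g, seed = 5, off_scale = 0.3)
  for (scheme in c("A", "B", "E")) {
    op <- assemble_operator(sig, scheme = scheme)
    expect_equal(apply_operator(op, u)$values,
                 slow_stencil_apply(sig, g, scheme, u), tolerance = 1e-11)
  }
})

test_that("matrix-free and sparse application paths agree", {
  g <- make_cube_grid(1, 8)
  sig <- random_pd_field(g, seed = 9)
  set.seed(13)
  u <- scalar_volume(g, array(rnorm(prod(g$n)), g$n))
  for (scheme in c("A", "B", "C", "D", "E")) {
    op <- assemble_operator(sig, scheme = scheme)
    a <- apply_operator(op, u)$values
    b <- apply_operator(op, u, method = "matrix_free")$values
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-12)
  }
  op <- assemble_operator(sig, scheme = "A")
  expect_equal(apply_operator(op, scalar_volume(g, 0))$values,
               array(0, g$n))
  expect_error(apply_operator(op, rnorm(10)), "shape")
  expect_error(assemble_operator(sig, scheme = "Z"))
})

test_that("scheme E samples off-diagonal components on the Eq-(5) nodes; C does not", {
  # perturbing sxy at one node must only touch matrix entries that a sxx
  # perturbation at the same node also touches (shared-stencil property)
  g <- make_cube_grid(1, 5)
  base <- random_pd_field(g, seed = 21)
  centre <- c(3, 3, 3)
  touched <- function(scheme, comp) {
    pert <- base
    pert[[comp]][centre[1], centre[2], centre[3]] <-
      pert[[comp]][centre[1], centre[2], centre[3]] + 1e-3
    d <- assemble_operator(pert, scheme = scheme)$A -
      assemble_operator(base, scheme = scheme)$A
    d <- as(abs(d), "TsparseMatrix")
    unique(d@i[d@x > 1e-12])
  }
  rows_dia_E <- union(touched("E", "xx"), touched("E", "yy"))
  expect_true(all(touched("E", "xy") %in% rows_dia_E))
  rows_dia_C <- union(touched("C", "xx"), touched("C", "yy"))
  expect_false(all(touched("C", "xy") %in% rows_dia_C))
})

test_that("dipole sources conserve current and snap to distinct nodes", {
  g <- make_cube_grid(0.2, 17)
  h <- g$h[1]
  src <- build_dipole_rhs(g, c(0, 0, 0), c(1, 0, 0), 2 * h, current = 3)
  expect_equal(sum(src$f$values) * prod(g$h), 0)
  nz <- which(src$f$values != 0)
  expect_length(nz, 2L)
  expect_equal(sort(src$f$values[nz]), c(-3, 3) / prod(g$h))
  # expected nodes from direct snapping arithmetic
  ctr <- (g$n[1] + 1) / 2
  expect_setequal(which(src$f$values != 0, arr.ind = TRUE)[, 1],
                  c(ctr - 1, ctr + 1))

  expect_error(build_dipole_rhs(g, c(0, 0, 0), c(1, 0, 0), h / 3),
               "degenerate")
  expect_error(build_dipole_rhs(g, c(0.1, 0, 0), c(1, 0, 0), 0.05),
               "outside")
})

test_that("operator export writes readable MatrixMarket coordinates", {
  g <- make_cube_grid(1, 5)
  op <- assemble_operator(random_pd_field(g, seed = 2), scheme = "E")
  path <- withr::local_tempfile(fileext = ".mtx")
  write_operator_mm(op, path)
  back <- Matrix::readMM(path)
  expect_lt(max(abs(back - op$A)), 1e-14)
  expect_true(file.exists(paste0(path, ".json")))
})
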