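test_that("smooth probe evaluates the stated closed forms", {
  g <- make_cube_grid(0.1, 9)     # odd n puts a node at the origin
  pr <- build_smooth_probe(g)
  ctr <- c(5, 5, 5)
  expect_equal(pr$sigma$xx[5, 5, 5], 12)
  expect_equal(pr$sigma$yy[5, 5, 5], 10)
  expect_equal(pr$sigma$zz[5, 5, 5], 8)
  expect_equal(pr$sigma$xy[5, 5, 5], sin(-3))
  expect_equal(pr$sigma$xz[5, 5, 5], sin(-3))
  # u vanishes on every box face
  expect_equal(max(abs(pr$u$values[c(1, 9), , ])), 0)
  expect_equal(max(abs(pr$u$values[, c(1, 9), ])), 0)
  expect_equal(max(abs(pr$u$values[, , c(1, 9)])), 0)
  expect_error(build_smooth_probe(make_cube_grid(0.3, 9)), "span")
})

test_that("hard-coded probe rhs matches a finite-difference divergence at O(h^2)", {
  # central-difference div(sigma grad u) of the stored fields, an oracle
  # independent of the analytic differentiation
  fd_divergence <- function(pr) {
    g <- pr$grid; h <- g$h
    u <- pr$u$values
    flux <- function(scomp, dax, uax) {
      du <- eitfdm:::shift_array(u, uax) - eitfdm:::shift_array(u, -uax)
      du <- du / (2 * h[which(uax != 0)])
      sdu <- pr$sigma[[scomp]] * du
      (eitfdm:::shift_array(sdu, dax) - eitfdm:::shift_array(sdu, -dax)) /
        (2 * h[which(dax != 0)])
    }
    ex <- c(1L, 0L, 0L); ey <- c(0L, 1L, 0L); ez <- c(0L, 0L, 1L)
    flux("xx", ex, ex) + flux("xy", ex, ey) + flux("xz", ex, ez) +
      flux("xy", ey, ex) + flux("yy", ey, ey) + flux("yz", ey, ez) +
      flux("xz", ez, ex) + flux("yz", ez, ey) + flux("zz", ez, ez)
  }
  errs <- vapply(c(17, 33), function(n) {
    pr <- build_smooth_probe(make_cube_grid(0.1, n))
    d <- fd_divergence(pr) - pr$f$values
    idx <- 3:(n - 2)   # the double shift needs two interior layers
    max(abs(d[idx, idx, idx]))
  }, numeric(1))
  expect_gt(log2(errs[1] / errs[2]), 1.7)
})

test_that("sphere model assigns shells by radius with air cladding", {
  g <- make_cube_grid(0.2, 33)    # node exactly at the centre
  spec <- sphere_model_spec(skull_tangential_ratio = 10)
  sig <- build_sphere_model(spec, g)
  ctr <- c(17, 17, 17)
  expect_equal(tensor_at(sig, ctr), diag(rep(0.25, 3)))
  corner <- c(2, 2, 2)
  expect_equal(tensor_at(sig, corner), diag(rep(1e-10, 3)))
  # CSF shell on the +x axis: r = 4h = 0.025 -> brain; r = 0.04375 -> CSF
  expect_equal(sig$xx[ctr[1] + 7, 17, 17], 1.79)
  # scalp: r = 0.075
  expect_equal(sig$xx[ctr[1] + 12, 17, 17], 0.44)
  check_positive_definite(sig)
  # 1:50 anisotropy still positive definite
  check_positive_definite(
    build_sphere_model(sphere_model_spec(skull_tangential_ratio = 50), g))
  expect_error(build_sphere_model(spec, make_cube_grid(0.1, 17)), "fit")
})

test_that("skull tensor is the rotated local diagonal", {
  sr <- 0.018; st <- 0.18
  m <- skull_tensor_at(c(0, 0, 0.06), c(0, 0, 0), sr, st)
  expect_equal(m, diag(c(st, st, sr)))
  mx <- skull_tensor_at(c(0.06, 0, 0), c(0, 0, 0), sr, st)
  expect_equal(mx, diag(c(sr, st, st)))
  set.seed(17)
  for (k in 1:5) {
    p <- rnorm(3)
    m <- skull_tensor_at(p, c(0, 0, 0), sr, st)
    expect_equal(m, t(m))
    expect_equal(sort(eigen(m, symmetric = TRUE)$values),
                 sort(c(sr, st, st)), tolerance = 1e-12)
  }
  expect_equal(skull_tensor_at(c(1, 2, 3), c(0, 0, 0), 0.3, 0.3),
               diag(rep(0.3, 3)))
  expect_error(skull_tensor_at(c(0, 0, 0), c(0, 0, 0), sr, st), "centre")

  # model-level: skull node on the +z axis with the 1:10 convention
  g <- make_cube_grid(0.2, 33)
  sig <- build_sphere_model(sphere_model_spec(skull_tangential_ratio = 10), g)
  # +z axis, r = 0.05625 (9 nodes above centre) is inside the skull shell
  m <- tensor_at(sig, c(17, 17, 26))
  expect_equal(m, diag(c(0.18, 0.18, 0.018)), tolerance = 1e-12)
})

test_that("clip insertion is bounded, idempotent and contrast-setting", {
  g <- make_cube_grid(0.2, 33)
  sig <- build_sphere_model(sphere_model_spec(skull_tangential_ratio = 10), g)
  clipped <- insert_pi_clip(sig, c(0, 0, 0.0575))
  expect_gte(max(clipped$xx) / min(clipped$xx), 2.5e6 / 1e-10)
  again <- insert_pi_clip(clipped, c(0, 0, 0.0575))
  expect_identical(again$xx, clipped$xx)
  # zero-volume box is a no-op
  expect_identical(insert_clip(sig, c(0, 0, 0.0575), c(0, 0, 0), 1)$xx,
                   sig$xx)
  expect_error(insert_clip(sig, c(0.3, 0, 0), rep(0.01, 3), 1), "outside")
})

test_that("DTI mapping rescales to trace 3*sigma_iso and keeps eigenvectors", {
  g <- regular_grid(4, 1)
  D <- tensor_field(g, xx = 2, yy = 1, zz = 1)
  sig <- dti_to_conductivity(D, 0.25)
  expect_equal(tensor_at(sig, c(1, 1, 1)), diag(c(0.375, 0.1875, 0.1875)))
  # isotropic limit: c*I -> sigma_iso*I
  expect_equal(tensor_at(dti_to_conductivity(
    isotropic_tensor_field(g, 7), 0.25), c(2, 2, 2)), diag(rep(0.25, 3)))
  # trace forced everywhere for a random field
  Dr <- random_pd_field(g, seed = 23)
  sr <- dti_to_conductivity(Dr, 0.25)
  expect_equal(sr$xx + sr$yy + sr$zz, array(0.75, g$n), tolerance = 1e-12)
  # principal directions preserved at a spot-checked node
  vD <- eigen(tensor_at(Dr, c(2, 3, 4)), symmetric = TRUE)$vectors
  vS <- eigen(tensor_at(sr, c(2, 3, 4)), symmetric = TRUE)$vectors
  expect_equal(abs(diag(crossprod(vD, vS))), rep(1, 3), tolerance = 1e-9)
  bad <- tensor_field(g, xx = 1, yy = 1, zz = 1, check = FALSE)
  bad$xx[2, 2, 2] <- -1; bad$yy[2, 2, 2] <- 0.5; bad$zz[2, 2, 2] <- 0.5
  expect_error(dti_to_conductivity(bad, 0.25), "node \\(2, 2, 2\\)")
})

test_that("geodesic montages are quasi-uniform at the requested radius", {
  m12 <- geodesic_sensors(12, radius = 0.084)
  expect_equal(nrow(m12), 12L)
  r <- sqrt(m12$x^2 + m12$y^2 + m12$z^2)
  expect_lt(max(abs(r - 0.084)) / 0.084, 1e-9)
  # icosahedron: every vertex has the same nearest-neighbour angle
  pts <- as.matrix(m12[, c("x", "y", "z")]) / 0.084
  ang <- acos(pmin(pmax(tcrossprod(pts), -1), 1))
  diag(ang) <- Inf
  nn <- apply(ang, 1, min)
  expect_lt(diff(range(nn)), 1e-9)

  m42 <- geodesic_sensors(42, radius = 1)
  expect_equal(nrow(m42), 42L)
  pts <- as.matrix(m42[, c("x", "y", "z")])
  ang <- acos(pmin(pmax(tcrossprod(pts), -1), 1))
  diag(ang) <- Inf
  expect_gt(min(ang), 0.28)
  expect_error(geodesic_sensors(3, 1), "at least 4")
})

test_that("sensor sampling interpolates trilinearly", {
  g <- make_cube_grid(0.2, 17)
  m <- geodesic_sensors(12, radius = 0.084)
  const <- scalar_volume(g, 5)
  expect_equal(sample_sensors(const, m), rep(5, 12))
  expect_equal(sample_sensors(const, m, reference = "average"), rep(0, 12))
  ax <- grid_axes(g)
  lin <- scalar_volume(g, array(rep(ax$x, times = 17 * 17), g$n))
  expect_equal(sample_sensors(lin, m), m$x, tolerance = 1e-12)
  far <- data.frame(x = 0.2, y = 0, z = 0)
  expect_error(sample_sensors(const, far), "outside")
})
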