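#' Smooth analytic probe problem
#'
#' Constructs the exact validation fixture used for order-of-accuracy
#' studies on the cube `[-a, a]^3`: the polynomial potential
#' `u = (x^2 - a^2)(y^2 - a^2)(z^2 - a^2)` (which vanishes on all six box
#' faces, matching the homogeneous Dirichlet boundary rows), a smooth
#' anisotropic conductivity tensor
#' `sxx = 6 (2 + r^2)`, `syy = 5 (2 + r^2)`, `szz = 4 (2 + r^2)`,
#' all off-diagonals `sin(r^2 - 3)` with `r^2 = x^2 + y^2 + z^2`,
#' and the right-hand side `f = div(sigma grad u)` obtained by analytic
#' differentiation and hard-coded in closed form.
#'
#' @param grid a cubic [regular_grid()] spanning exactly `[-a, a]^3`.
#' @param a half edge length in metres (default 0.05, the 0.1 m
#'   fictitious box of the validation studies).
#' @return An object of class `"probe_solution"`: fields `grid`, `u`
#'   (exact potential, [scalar_volume()]), `sigma` ([tensor_field()]),
#'   `f` ([scalar_volume()]), `a`.
#' @export
build_smooth_probe <- function(grid, a = 0.05) {
  stopifnot(inherits(grid, "regular_grid"))
  ax <- grid_axes(grid)
  lo <- c(ax$x[1], ax$y[1], ax$z[1])
  hi <- c(ax$x[grid$n[1]], ax$y[grid$n[2]], ax$z[grid$n[3]])
  if (!isTRUE(all.equal(lo, rep(-a, 3))) ||
      !isTRUE(all.equal(hi, rep(a, 3))))
    stop(sprintf("grid must span [-a, a]^3 with a = %g", a), call. = FALSE)
  n <- grid$n
  X <- array(rep(ax$x, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ax$y, each = n[1]), times = n[3]), n)
  Z <- array(rep(ax$z, each = n[1] * n[2]), n)
  r2 <- X^2 + Y^2 + Z^2
  px <- X^2 - a^2; py <- Y^2 - a^2; pz <- Z^2 - a^2
  u <- px * py * pz
  s <- sin(r2 - 3)
  sigma <- tensor_field(grid,
                        xx = 6 * (2 + r2), yy = 5 * (2 + r2),
                        zz = 4 * (2 + r2),
                        xy = s, xz = s, yz = s)
  cc <- cos(r2 - 3)
  ux <- 2 * X * py * pz; uy <- 2 * Y * px * pz; uz <- 2 * Z * px * py
  uxx <- 2 * py * pz; uyy <- 2 * px * pz; uzz <- 2 * px * py
  uxy <- 4 * X * Y * pz; uxz <- 4 * X * Z * py; uyz <- 4 * Y * Z * px
  gx <- 12 * X + 2 * Y * cc + 2 * Z * cc
  gy <- 2 * X * cc + 10 * Y + 2 * Z * cc
  gz <- 2 * X * cc + 2 * Y * cc + 8 * Z
  f <- sigma$xx * uxx + sigma$yy * uyy + sigma$zz * uzz +
    2 * s * (uxy + uxz + uyz) + gx * ux + gy * uy + gz * uz
  structure(list(grid = grid, u = scalar_volume(grid, u), sigma = sigma,
                 f = scalar_volume(grid, f), a = a),
            class = "probe_solution")
}

#' Four-shell spherical head model specification
#'
#' Printed defaults: shell outer radii 0.084 (scalp), 0.065 (skull), 0.05
#' (CSF), 0.03 m (brain); conductivities 0.44, 0.018, 1.79, 0.250 S/m;
#' air cladding 1e-10 S/m.  The skull layer may be anisotropic with a
#' tangential-to-radial ratio (>= 1).  Because the literature leaves
#' ambiguous which component the printed skull value denotes, the
#' `convention` switch selects whether 0.018 S/m is the radial
#' conductivity (default; tangential = ratio x radial, the physiological
#' tangentially-dominant reading) or the tangential one (radial =
#' value / ratio).
#'
#' @param shell_radii four outer radii in metres, strictly decreasing
#'   (scalp, skull, CSF, brain).
#' @param shell_conductivities four isotropic conductivities (S/m) in the
#'   same order.
#' @param skull_radial_conductivity skull conductivity (S/m) entering the
#'   anisotropy construction (interpreted per `convention`).
#' @param skull_tangential_ratio tangential : radial ratio, >= 1.
#' @param air_conductivity fictitious-domain air cladding (S/m).
#' @param centre sphere centre (metres).
#' @param convention `"printed_radial"` or `"printed_tangential"`.
#' @return A list of class `"sphere_model_spec"`.
#' @export
sphere_model_spec <- function(shell_radii = c(0.084, 0.065, 0.05, 0.03),
                              shell_conductivities = c(0.44, 0.018, 1.79,
                                                       0.250),
                              skull_radial_conductivity = 0.018,
                              skull_tangential_ratio = 1,
                              air_conductivity = 1e-10,
                              centre = c(0, 0, 0),
                              convention = c("printed_radial",
                                             "printed_tangential")) {
  convention <- match.arg(convention)
  if (length(shell_radii) != 4L || any(diff(shell_radii) >= 0))
    stop("shell radii must be four strictly decreasing values",
         call. = FALSE)
  if (length(shell_conductivities) != 4L || any(shell_conductivities <= 0))
    stop("shell conductivities must be four positive values", call. = FALSE)
  if (skull_radial_conductivity <= 0 || air_conductivity <= 0)
    stop("conductivities must be positive", call. = FALSE)
  if (skull_tangential_ratio < 1)
    stop("tangential:radial ratio must be >= 1", call. = FALSE)
  structure(list(shell_radii = shell_radii,
                 shell_conductivities = shell_conductivities,
                 skull_radial_conductivity = skull_radial_conductivity,
                 skull_tangential_ratio = skull_tangential_ratio,
                 air_conductivity = air_conductivity,
                 centre = as.numeric(centre),
                 convention = convention),
            class = "sphere_model_spec")
}

# Resolved (radial, tangential) skull conductivities for a spec.
skull_conductivities <- function(spec) {
  if (spec$convention == "printed_radial") {
    sr <- spec$skull_radial_conductivity
    st <- sr * spec$skull_tangential_ratio
  } else {
    st <- spec$skull_radial_conductivity
    sr <- st / spec$skull_tangential_ratio
  }
  c(radial = sr, tangential = st)
}

#' Anisotropic skull tensor at a point
#'
#' The local skull tensor is diagonal, `diag(st, st, sr)`, in a frame
#' whose third axis is the radial direction; rotating into global
#' coordinates gives the closed form `st I + (sr - st) rhat rhat^T`, a
#' symmetric matrix with eigenvalues exactly `{sr, st, st}`.
#'
#' @param point position (metres, length 3), distinct from `centre`.
#' @param centre sphere centre.
#' @param sigma_radial radial conductivity (S/m).
#' @param sigma_tangential tangential conductivity (S/m).
#' @return A symmetric 3x3 matrix (S/m).
#' @export
skull_tensor_at <- function(point, centre, sigma_radial, sigma_tangential) {
  d <- as.numeric(point) - as.numeric(centre)
  r <- sqrt(sum(d^2))
  if (r == 0)
    stop("radial direction undefined at the sphere centre", call. = FALSE)
  rhat <- d / r
  sigma_tangential * diag(3) +
    (sigma_radial - sigma_tangential) * tcrossprod(rhat)
}

#' Build the four-shell sphere conductivity volume
#'
#' Assigns every node by its radius from the sphere centre: brain, CSF and
#' scalp get isotropic diagonal tensors, skull nodes the anisotropic
#' tensor of [skull_tensor_at()], everything beyond the scalp radius the
#' air-cladding conductivity.  Shells are half-open and outer-exclusive: a
#' node exactly on a shell boundary belongs to the inner shell.
#'
#' @param spec a [sphere_model_spec()].
#' @param grid a [regular_grid()]; the sphere must fit with at least one
#'   air node of margin.
#' @return A [tensor_field()].
#' @export
build_sphere_model <- function(spec, grid) {
  stopifnot(inherits(spec, "sphere_model_spec"),
            inherits(grid, "regular_grid"))
  ax <- grid_axes(grid)
  margin <- min(spec$centre[1] - ax$x[1], ax$x[grid$n[1]] - spec$centre[1],
                spec$centre[2] - ax$y[1], ax$y[grid$n[2]] - spec$centre[2],
                spec$centre[3] - ax$z[1], ax$z[grid$n[3]] - spec$centre[3])
  if (spec$shell_radii[1] > margin - max(grid$h))
    stop("sphere does not fit inside the grid with an air margin",
         call. = FALSE)
  n <- grid$n
  X <- array(rep(ax$x - spec$centre[1], times = n[2] * n[3]), n)
  Y <- array(rep(rep(ax$y - spec$centre[2], each = n[1]), times = n[3]), n)
  Z <- array(rep(ax$z - spec$centre[3], each = n[1] * n[2]), n)
  R <- sqrt(X^2 + Y^2 + Z^2)
  rr <- spec$shell_radii          # scalp, skull, csf, brain (descending)
  cc <- spec$shell_conductivities
  iso <- array(spec$air_conductivity, n)
  iso[R <= rr[1]] <- cc[1]        # scalp
  iso[R <= rr[3]] <- cc[3]        # CSF
  iso[R <= rr[4]] <- cc[4]        # brain
  xx <- yy <- zz <- iso
  xy <- xz <- yz <- array(0, n)
  skull <- R > rr[3] & R <= rr[2]
  sk <- skull_conductivities(spec)
  if (any(skull)) {
    rx <- X[skull] / R[skull]; ry <- Y[skull] / R[skull]
    rz <- Z[skull] / R[skull]
    dd <- sk[["radial"]] - sk[["tangential"]]
    xx[skull] <- sk[["tangential"]] + dd * rx^2
    yy[skull] <- sk[["tangential"]] + dd * ry^2
    zz[skull] <- sk[["tangential"]] + dd * rz^2
    xy[skull] <- dd * rx * ry
    xz[skull] <- dd * rx * rz
    yz[skull] <- dd * ry * rz
  }
  tensor_field(grid, xx = xx, yy = yy, zz = zz, xy = xy, xz = xz, yz = yz)
}

#' Insert an isotropic axis-aligned box (e.g. a surgical clip)
#'
#' Nodes strictly inside the box (centre +- dims/2) are overwritten with
#' the isotropic tensor `diag(conductivity)`; all other nodes are
#' unchanged.  A zero-volume box leaves the field untouched and the
#' operation is idempotent.
#'
#' @param sigma a [tensor_field()].
#' @param box_centre centre of the box (metres).
#' @param box_dims edge lengths (metres, length 3).
#' @param conductivity isotropic conductivity of the insert (S/m), e.g.
#'   2.5e6 for titanium.
#' @return The modified [tensor_field()].
#' @export
insert_clip <- function(sigma, box_centre, box_dims, conductivity) {
  stopifnot(inherits(sigma, "tensor_field"))
  grid <- sigma$grid
  ax <- grid_axes(grid)
  box_dims <- rep_len(as.numeric(box_dims), 3L)
  if (any(box_dims <= 0)) return(sigma)
  lo <- as.numeric(box_centre) - box_dims / 2
  hi <- as.numeric(box_centre) + box_dims / 2
  glo <- c(ax$x[1], ax$y[1], ax$z[1])
  ghi <- c(ax$x[grid$n[1]], ax$y[grid$n[2]], ax$z[grid$n[3]])
  if (any(lo < glo - 1e-12) || any(hi > ghi + 1e-12))
    stop("clip box lies outside the grid", call. = FALSE)
  inx <- ax$x >= lo[1] & ax$x <= hi[1]
  iny <- ax$y >= lo[2] & ax$y <= hi[2]
  inz <- ax$z >= lo[3] & ax$z <= hi[3]
  if (!any(inx) || !any(iny) || !any(inz)) return(sigma)
  sigma$xx[inx, iny, inz] <- conductivity
  sigma$yy[inx, iny, inz] <- conductivity
  sigma$zz[inx, iny, inz] <- conductivity
  sigma$xy[inx, iny, inz] <- 0
  sigma$xz[inx, iny, inz] <- 0
  sigma$yz[inx, iny, inz] <- 0
  sigma
}

#' Insert a Pi-shaped titanium clip
#'
#' Union of three axis-aligned boxes forming the Greek letter Pi in the
#' x-z plane: two vertical legs and a top bar, overall outline 12 mm x 12
#' mm with a 2 mm x 4 mm cross-section by default (the synthetic stand-in
#' for a post-surgical skull clip).
#'
#' @inheritParams insert_clip
#' @param centre centre of the Pi outline (metres).
#' @param outline in-plane outline size (metres; default 0.012).
#' @param cross_section c(thickness, depth) of the bar/legs (metres;
#'   default c(0.002, 0.004)).
#' @param conductivity insert conductivity (S/m; default titanium 2.5e6).
#' @return The modified [tensor_field()].
#' @export
insert_pi_clip <- function(sigma, centre, outline = 0.012,
                           cross_section = c(0.002, 0.004),
                           conductivity = 2.5e6) {
  th <- cross_section[1]; dp <- cross_section[2]
  half <- outline / 2
  # top bar along x at the top of the outline
  sigma <- insert_clip(sigma, centre + c(0, 0, half - th / 2),
                       c(outline, dp, th), conductivity)
  # two legs descending in z
  leg_h <- outline - th
  for (sx in c(-1, 1))
    sigma <- insert_clip(sigma,
                         centre + c(sx * (half - th / 2), 0, -th / 2),
                         c(th, dp, leg_h), conductivity)
  sigma
}

#' Map a diffusion-tensor volume to a conductivity volume
#'
#' Per-node scaling `sigma = 3 sigma_iso D / tr(D)`: the conductivity
#' tensor shares the eigenvectors (principal directions) of the diffusion
#' tensor and its trace is exactly `3 sigma_iso` everywhere.
#'
#' @param D a [tensor_field()] of diffusion tensors (any units; only the
#'   shape matters).
#' @param sigma_iso reference isotropic conductivity (S/m), e.g. 0.25 for
#'   brain white matter.
#' @return A [tensor_field()] of conductivities.
#' @export
dti_to_conductivity <- function(D, sigma_iso) {
  stopifnot(inherits(D, "tensor_field"))
  tr <- D$xx + D$yy + D$zz
  if (any(tr <= 0)) {
    ijk <- which(array(tr <= 0, D$grid$n), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive diffusion-tensor trace at node (%d, %d, %d)",
      ijk[1], ijk[2], ijk[3]), call. = FALSE)
  }
  s <- 3 * sigma_iso / tr
  tensor_field(D$grid, xx = D$xx * s, yy = D$yy * s, zz = D$zz * s,
               xy = D$xy * s, xz = D$xz * s, yz = D$yz * s)
}
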