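# Reproducible performance studies: order of accuracy, preconditioner x
# scheme x resolution iteration grids, skull-anisotropy sweep, and the
# extreme-heterogeneity stress test.

# Shared defaults for the sphere experiments.  The printed scalp radius
# (0.084 m) does not fit the 0.1 m probe box, so the sphere studies use a
# 0.2 m fictitious cube; the dipole is a tangential source-sink pair on
# the equator at mid outer shell (r = (0.065 + 0.084)/2 m).
SPHERE_BOX_EDGE <- 0.2
SPHERE_DIPOLE_RADIUS <- (0.065 + 0.084) / 2
SPHERE_DIPOLE_SEPARATION <- 0.01
SPHERE_DIPOLE_CURRENT <- 1e-6

sphere_experiment_inputs <- function(n, ratio = 10,
                                     spec = NULL, clip = FALSE) {
  grid <- make_cube_grid(SPHERE_BOX_EDGE, n)
  if (is.null(spec)) spec <- sphere_model_spec(skull_tangential_ratio = ratio)
  sigma <- build_sphere_model(spec, grid)
  if (clip) sigma <- insert_pi_clip(sigma, c(0, 0, 0.0575))
  rhs <- build_dipole_rhs(grid, c(SPHERE_DIPOLE_RADIUS, 0, 0), c(0, 1, 0),
                          SPHERE_DIPOLE_SEPARATION, SPHERE_DIPOLE_CURRENT)
  list(grid = grid, sigma = sigma, rhs = rhs)
}

probe_experiment_inputs <- function(n, a = 0.05) {
  grid <- make_cube_grid(2 * a, n)
  pr <- build_smooth_probe(grid, a)
  list(grid = grid, sigma = pr$sigma, rhs = pr$f, probe = pr)
}

run_one <- function(model, op, rhs, preconditioner, config, exact = NULL) {
  P <- make_preconditioner(preconditioner, op,
                           fourier_coefficient = config$fourier_coefficient,
                           fj_composition = config$fj_composition)
  res <- tryCatch(
    if (config$method == "bicg") bicg_solve(op, rhs, P, config)
    else bicgstab_solve(op, rhs, P, config),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(data.frame(model = model, scheme = op$scheme,
                      preconditioner = preconditioner, n = op$grid$n[1],
                      tolerance = config$tolerance, iterations = NA_integer_,
                      converged = FALSE, final_residual = NA_real_,
                      error_l2 = NA_real_, error_max = NA_real_,
                      breakdown = conditionMessage(res),
                      stringsAsFactors = FALSE))
  }
  el2 <- emax <- NA_real_
  if (!is.null(exact)) {
    d <- res$potential$values - exact$values
    el2 <- sqrt(sum(d^2) / sum(exact$values^2))
    emax <- max(abs(d))
  }
  data.frame(model = model, scheme = op$scheme,
             preconditioner = preconditioner, n = op$grid$n[1],
             tolerance = config$tolerance, iterations = res$iterations,
             converged = res$converged, final_residual = res$final_residual,
             error_l2 = el2, error_max = emax,
             breakdown = if (is.null(res$breakdown)) NA_character_
             else res$breakdown,
             stringsAsFactors = FALSE)
}

#' Order-of-accuracy study on the smooth probe
#'
#' Solves the probe problem on a sequence of grids (nested by factor two)
#' and reports, per grid pair, the observed convergence order
#' `log(err(h1)/err(h2)) / log(h1/h2)` of the relative L2 solution error
#' against the exact potential.  All five mixed-derivative schemes are
#' second order, so observed orders concentrate near 2.
#'
#' @param scheme mixed-derivative scheme tag.
#' @param grids node counts, at least three, each about double the last.
#' @param a probe half edge (m).
#' @param tolerance solver tolerance; keep well below the discretization
#'   error (default 1e-9) so the iteration error does not pollute the
#'   order estimate.
#' @param preconditioner passed to the solver (default Fourier-Jacobi).
#' @param initial_guess `"zero"` (default) or `"exact"` (sanity variant:
#'   starts at the exact solution, converging in 0-1 iterations).
#' @return A list with `records` (one row per grid) and `orders` (one per
#'   grid pair).
#' @export
convergence_order_study <- function(scheme = "A", grids = c(16, 32, 64),
                                    a = 0.05, tolerance = 1e-9,
                                    preconditioner = "fourier_jacobi",
                                    initial_guess = c("zero", "exact")) {
  initial_guess <- match.arg(initial_guess)
  if (length(grids) < 2L)
    stop("need at least two grid sizes", call. = FALSE)
  records <- NULL
  errs <- hs <- numeric(length(grids))
  for (gi in seq_along(grids)) {
    inp <- probe_experiment_inputs(grids[gi], a)
    cfg <- solver_config(scheme = scheme, preconditioner = preconditioner,
                         tolerance = tolerance, max_iterations = 3000L,
                         initial_guess = if (initial_guess == "exact")
                           inp$probe$u else NULL)
    op <- assemble_operator(inp$sigma, scheme = scheme)
    rec <- run_one("probe", op, inp$rhs, preconditioner, cfg,
                   exact = inp$probe$u)
    if (!isTRUE(rec$converged))
      stop(sprintf(
        "order study aborted: no convergence at n = %d (residual %.3e)",
        grids[gi], rec$final_residual), call. = FALSE)
    records <- rbind(records, rec)
    errs[gi] <- rec$error_l2
    hs[gi] <- inp$grid$h[1]
  }
  orders <- log(errs[-length(errs)] / errs[-1]) /
    log(hs[-length(hs)] / hs[-1])
  list(records = records, errors = errs, orders = orders)
}

#' Iteration-count grid over schemes, preconditioners and resolutions
#'
#' One solver run per combination; individual non-convergence is recorded
#' in the output, never fatal.
#'
#' @param model `"probe"` or `"sphere"`.
#' @param schemes,preconditioners,grids vectors of combinations to run.
#' @param tolerance relative residual tolerance.
#' @param max_iterations per-run iteration cap.
#' @param ratio skull anisotropy ratio for the sphere model.
#' @param csv optional path: results are also written as CSV.
#' @return A data frame of experiment records.
#' @export
iteration_grid <- function(model = c("probe", "sphere"),
                           schemes = "A",
                           preconditioners = "fourier_jacobi",
                           grids = c(32, 64),
                           tolerance = 1e-5, max_iterations = 2000L,
                           ratio = 10, csv = NULL) {
  model <- match.arg(model)
  out <- NULL
  for (n in grids) {
    inp <- if (model == "probe") probe_experiment_inputs(n)
    else sphere_experiment_inputs(n, ratio = ratio)
    for (scheme in schemes) {
      op <- assemble_operator(inp$sigma, scheme = scheme)
      for (pre in preconditioners) {
        cfg <- solver_config(scheme = scheme, preconditioner = pre,
                             tolerance = tolerance,
                             max_iterations = max_iterations)
        out <- rbind(out, run_one(model, op, inp$rhs, pre, cfg,
                                  exact = inp$probe$u))
      }
    }
  }
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

# Fixed averaging set for the anisotropy sweep: six tangential dipoles,
# two per axis, at mid outer shell radius.
sweep_dipoles <- function() {
  r <- SPHERE_DIPOLE_RADIUS
  list(list(pos = c(r, 0, 0), ori = c(0, 1, 0)),
       list(pos = c(-r, 0, 0), ori = c(0, 1, 0)),
       list(pos = c(0, r, 0), ori = c(0, 0, 1)),
       list(pos = c(0, -r, 0), ori = c(0, 0, 1)),
       list(pos = c(0, 0, r), ori = c(1, 0, 0)),
       list(pos = c(0, 0, -r), ori = c(1, 0, 0)))
}

#' Skull anisotropy-ratio sweep
#'
#' Runs the sphere model over a list of tangential:radial skull ratios
#' and reports the FJ-BiCG iteration count per ratio, averaged over a
#' fixed set of six dipoles (two per axis, tangential, at mid outer
#' shell).
#'
#' @param ratios skull anisotropy ratios, each >= 1.
#' @param n grid nodes per axis.
#' @param scheme mixed-derivative scheme (default E, the shared-stencil
#'   scheme).
#' @param preconditioner solver preconditioner.
#' @param tolerance relative residual tolerance.
#' @param csv optional CSV output path.
#' @return A list with `records` (per ratio x dipole) and `summary` (mean
#'   iterations per ratio).
#' @export
anisotropy_sweep <- function(ratios = c(1, 10, 50), n = 64, scheme = "E",
                             preconditioner = "fourier_jacobi",
                             tolerance = 1e-5, csv = NULL) {
  if (any(ratios < 1)) stop("ratios must be >= 1", call. = FALSE)
  records <- NULL
  for (ratio in ratios) {
    inp <- sphere_experiment_inputs(n, ratio = ratio)
    op <- assemble_operator(inp$sigma, scheme = scheme)
    cfg <- solver_config(scheme = scheme, preconditioner = preconditioner,
                         tolerance = tolerance, max_iterations = 2000L)
    for (di in seq_along(sweep_dipoles())) {
      d <- sweep_dipoles()[[di]]
      rhs <- build_dipole_rhs(inp$grid, d$pos, d$ori,
                              SPHERE_DIPOLE_SEPARATION,
                              SPHERE_DIPOLE_CURRENT)
      rec <- run_one("sphere", op, rhs, preconditioner, cfg)
      rec$ratio <- ratio
      rec$dipole <- di
      records <- rbind(records, rec)
    }
  }
  summary <- stats::aggregate(iterations ~ ratio, data = records, FUN = mean)
  if (!is.null(csv)) utils::write.csv(records, csv, row.names = FALSE)
  list(records = records, summary = summary)
}

#' Extreme-heterogeneity stress test
#'
#' Builds the harshest model this package generates -- the anisotropic
#' sphere with a titanium clip in the skull, embedded in the air-clad
#' fictitious box -- verifies its conductivity contrast meets
#' `contrast_target`, and solves with the FJ-preconditioned BiCG for the
#' requested schemes.  With `contrast_target <= 1` a homogeneous
#' unit-conductivity volume is solved instead (the preconditioner then
#' nearly equals the operator).
#'
#' @param contrast_target required max/min conductivity ratio (the
#'   titanium/air default reaches 2.5e16).
#' @param n grid nodes per axis.
#' @param schemes schemes to run (default the two robust ones, A and E).
#' @param tolerance relative residual tolerance.
#' @param max_iterations per-run cap.
#' @return A data frame of experiment records with an extra `contrast`
#'   column.
#' @export
heterogeneity_stress <- function(contrast_target = 1e16, n = 64,
                                 schemes = c("A", "E"), tolerance = 1e-5,
                                 max_iterations = 2000L) {
  if (contrast_target <= 1) {
    grid <- make_cube_grid(SPHERE_BOX_EDGE, n)
    sigma <- isotropic_tensor_field(grid, 1)
    rhs <- build_dipole_rhs(grid, c(SPHERE_DIPOLE_RADIUS, 0, 0), c(0, 1, 0),
                            SPHERE_DIPOLE_SEPARATION, SPHERE_DIPOLE_CURRENT)
    inp <- list(grid = grid, sigma = sigma, rhs = rhs)
    contrast <- 1
  } else {
    inp <- sphere_experiment_inputs(n, ratio = 10, clip = TRUE)
    contrast <- max(inp$sigma$xx) / min(inp$sigma$xx)
    if (contrast < contrast_target)
      stop(sprintf("model contrast %.3g below target %.3g", contrast,
                   contrast_target), call. = FALSE)
  }
  out <- NULL
  for (scheme in schemes) {
    op <- assemble_operator(inp$sigma, scheme = scheme)
    cfg <- solver_config(scheme = scheme, preconditioner = "fourier_jacobi",
                         tolerance = tolerance,
                         max_iterations = max_iterations)
    out <- rbind(out, run_one("sphere+clip", op, inp$rhs, "fourier_jacobi",
                              cfg))
  }
  out$contrast <- contrast
  out
}
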