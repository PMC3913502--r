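# Memoised expensive fixtures shared across acceptance-test blocks (the
# 128^3 operators take ~15 s each to assemble; several criteria reuse
# them).
.acc_cache <- new.env(parent = emptyenv())

acc_get <- function(key, fn) {
  if (!exists(key, envir = .acc_cache, inherits = FALSE))
    assign(key, fn(), envir = .acc_cache)
  get(key, envir = .acc_cache, inherits = FALSE)
}

acc_drop <- function(...) {
  keys <- intersect(c(...), ls(.acc_cache))
  if (length(keys)) rm(list = keys, envir = .acc_cache)
  invisible(gc(verbose = FALSE))
}

probe_op <- function(n, scheme = "A") {
  acc_get(sprintf("probe_%d_%s", n, scheme), function() {
    grid <- make_cube_grid(0.1, n)
    pr <- build_smooth_probe(grid)
    list(op = assemble_operator(pr$sigma, scheme = scheme), probe = pr)
  })
}

sphere_solve_iters <- function(n, scheme, tolerance = 1e-5) {
  acc_get(sprintf("sphere_iters_%d_%s", n, scheme), function() {
    grid <- make_cube_grid(0.2, n)
    sigma <- build_sphere_model(sphere_model_spec(skull_tangential_ratio = 10),
                                grid)
    op <- assemble_operator(sigma, scheme = scheme)
    rhs <- build_dipole_rhs(grid, c(0.0745, 0, 0), c(0, 1, 0), 0.01, 1e-6)
    P <- make_preconditioner("fourier_jacobi", op)
    res <- bicg_solve(op, rhs, P,
                      solver_config(tolerance = tolerance,
                                    max_iterations = 2000L))
    list(iterations = res$iterations, converged = res$converged)
  })
}
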