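Package: eitfdm
Title: Finite-Difference Forward Solver for Anisotropic EEG/EIT Poisson
    Problems
Version: 0.1.0
Authors@R:
    person("Forward", "Solver Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Solves the anisotropic Poisson equation governing the EEG and
    EIT forward problems on a regular grid using a fictitious-domain
    embedding, a 19-point finite-difference stencil with five
    mixed-derivative discretization schemes, and preconditioned BiCG /
    BiCGStab Krylov iteration.  Preconditioners include Jacobi (diagonal),
    a fast Poisson (discrete sine transform) solver for the
    constant-coefficient Dirichlet Laplacian, and the combined
    Fourier-Jacobi preconditioner whose iteration counts are independent
    of grid resolution.  Ships fixture generators for a smooth analytic
    probe problem, a four-shell anisotropic spherical head model with
    optional titanium-clip insertions, a diffusion-tensor to conductivity
    mapping, and geodesic sensor montages, plus reproducible
    order-of-accuracy and preconditioner performance studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
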