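---
title: "Methods: the anisotropic finite-difference forward solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the anisotropic finite-difference forward solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

EEG and EIT forward modelling reduce, in the quasistatic regime, to the
anisotropic Poisson equation

$$\nabla \cdot (\sigma \nabla u) = f,$$

where $\sigma(x,y,z)$ is a symmetric positive-definite 3×3 conductivity
tensor field (S/m), $f$ the impressed current-source density and $u$ the
electric potential.  Head tissue makes $\sigma$ both strongly
heterogeneous (CSF ≈ 1.79 S/m against skull ≈ 0.018 S/m, air cladding
down at $10^{-10}$ S/m, metal implants up at $2.5\times10^{6}$ S/m) and
anisotropic (skull and white matter conduct better tangentially /
along fibres).

This package solves that equation on a regular node-centered grid using
the *fictitious domain* idea: the head (or any model volume) is embedded
in a cube padded with near-zero "air" conductivity.  Zero-flux behaviour
on the physical surface is then implicit — current cannot escape into
the air — while the cube faces carry homogeneous Dirichlet rows, which
is what the fast preconditioner needs.  Air must be *small positive*
($10^{-10}$ S/m by default), never zero, so the operator stays
invertible; the tensor-field constructor rejects non-positive-definite
nodes (Sylvester's criterion on all three principal minors, equivalent
to the eigenvalue test and vectorizable).

## Discretization

The operator is assembled as the 19-point stencil
`assemble_operator(sigma, scheme =)`: per axis the conservative
three-point second-difference with face-averaged coefficients
$\sigma^{0\pm} = (\sigma_0 + \sigma_{\pm})/2$, plus, per coordinate
plane, one of five second-order approximations of the mixed-derivative
pair $\partial_1(\sigma_{12}\partial_2 u) + \partial_2(\sigma_{12}
\partial_1 u)$.  The sign convention is fixed once: the assembled matrix
is the *negative-definite* discrete $\nabla\cdot\sigma\nabla$ (interior
centre coefficient negative; for unit isotropic $\sigma$ an interior row
is the 7-point Laplacian with $+1/h^2$ neighbours and $-6/h^2$ centre),
and the Fourier preconditioner inverts the constant-coefficient operator
with the *same* sign, so in the homogeneous isotropic limit the
preconditioner equals the operator exactly.

The five mixed-derivative schemes, reconstructed from their defining
properties (the equation typesetting in the source literature contains repeated
sub-expressions that cancel; every reconstruction below is verified
second-order on the analytic probe):

* **A** — the conservative average of the four one-sided splittings
  $\tfrac14[\Delta_1^+(\sigma\Delta_2^+) + \Delta_1^-(\sigma\Delta_2^-)
  + \Delta_1^+(\sigma\Delta_2^-) + \Delta_1^-(\sigma\Delta_2^+)]$ with
  plain node coefficients.  The centre-node coefficient terms cancel
  algebraically, so **A assembles a matrix identical to D** for *every*
  tensor field; both tags are kept because they are distinct
  constructions that happen to coincide.
* **B** — the upwind splitting $\sigma^{\pm} = \sigma \pm |\sigma|$ (as
  printed, *without* a ½ factor: with the scheme's $1/(4h_1h_2)$
  prefactor the printed form is exactly consistent, since
  $\sigma^++\sigma^-=2\sigma$).  The positive part pairs aligned
  one-sided differences, the negative part opposed ones, which yields
  non-negative corner coefficients and a maximum principle under the
  usual diagonal-dominance condition.  `scheme_b_split(halved = TRUE)`
  exposes the conventional halved splitting for comparison; it halves
  the mixed term and is *inconsistent* — it exists only because the
  printed convention is unusual enough to warrant a side-by-side check.
* **C** — one-sided differences in the $i\pm1$ columns with
  *edge-averaged* coefficients (extra averaging nodes in the stencil).
* **D** — the four-point scheme with node coefficients at $i\pm1$, the
  generalization of the constant-coefficient cross stencil.
* **E** — flux form: $[\sigma^{0+}(\overline{\partial_2 u})_{i+1/2} -
  \sigma^{0-}(\overline{\partial_2 u})_{i-1/2}]/h_1$ with the *same*
  face averages as the second-derivative scheme, so diagonal and
  off-diagonal tensor components are sampled at the same stencil nodes.
  This shared-stencil property preserves local positive definiteness
  across sharp tissue interfaces and makes E the recommended scheme for
  layered models.

For constant coefficients A, C, D and E assemble entrywise-identical
matrices.  Interior row sums vanish identically (discrete conservation);
boundary rows are the Dirichlet identity.  Rows keep physical units (no
$h^2$ pre-scaling) so the preconditioner's closed-form eigenvalues apply
unchanged.

Dipolar sources are deposited as two monopole densities $\pm I/(h_x h_y
h_z)$ on the nodes nearest the endpoints $\mathbf{p} \pm
\tfrac{s}{2}\hat{\mathbf{d}}$, so the discrete volume integral of $f$
equals the injected current exactly and dipolar balance is exact.

## Krylov solution and preconditioning

The system is nonsymmetric (heterogeneity plus boundary rows), so the
drivers are preconditioned BiCG (`bicg_solve`, the default) and
BiCGStab (`bicgstab_solve`).  Stopping uses the *true* relative residual
$\|f - AU\|_2/\|f\|_2$: the cheap recurrence residual is monitored every
iteration, and once it passes the tolerance the true residual is
recomputed and must pass as well.  The default tolerance is $10^{-5}$,
the working accuracy of all performance studies; the initial guess is
always zero so iteration counts are reproducible.

Three preconditioners:

* **Jacobi** — $z = r \oslash \mathrm{diag}(A)$.  Handles heterogeneity
  but not resolution: its iteration counts grow roughly linearly with
  the per-axis node count (measured on the probe: 71 at $N{=}32$, 148 at
  $N{=}64$, 323 at $N{=}128$).
* **Fourier** — the exact inverse of the constant-coefficient 7-point
  Dirichlet Laplacian $L_0$, applied via the 3D type-I discrete sine
  transform on the interior block with closed-form eigenvalues
  $\lambda_{ijk} = \sigma_0 \sum_{\text{axes}} (4/h^2)\sin^2(\pi
  m/(2(n-1)))$ over interior modes $m = 1..n-2$ (boundary values pass
  through).  The DST is realized as a dense sine-matrix multiplication
  rather than an FFT: the interior length $n-2$ for the canonical grids
  gives odd-extension FFT lengths with large prime factors ($n{=}128
  \Rightarrow 254 = 2\cdot127$), which R's mixed-radix FFT handles
  poorly, while the $\mathcal{O}(m^4)$ BLAS route is exact and takes
  well under a second per apply at $126^3$.
* **Fourier–Jacobi (FJ)** — the workhorse.  The combination formula is
  an interpretation (two are shipped):
  - `sequential` (default): $z = L_0^{-1}(r \oslash D)$ with
    $D=|\mathrm{diag}(A)|$, and the matching transpose apply for the
    BiCG shadow recurrence.
  - `symmetric`: $z = D^{-1/2} L_0^{-1} D^{-1/2} r$.

  The symmetric form was the a-priori design choice (it preserves the
  symmetry structure and collapses to pure Fourier in the homogeneous
  limit), but measurement reversed the decision: on the four-shell
  sphere at $\varepsilon = 10^{-5}$ the symmetric form needs 50–58
  iterations at $N{=}48$ and suffers floating-point overflow of the
  shadow recurrence at $N{=}64$, while the sequential form converges in
  21–24 iterations *flat across resolutions*, reproducing the reference
  behaviour of the method.  Hence `sequential` is the default; the
  symmetric variant remains available for study.

Numerical safeguards worth knowing about: (i) with conductivity
contrasts of $10^{16}$ the preconditioned shadow recurrence is strongly
non-normal and can grow by several orders of magnitude per iteration;
BiCG iterates for the solution are invariant under a joint rescaling of
(shadow residual, shadow direction, previous $\rho$), so the driver
renormalizes the shadow whenever its norm leaves $[10^{-50},10^{50}]$.
(ii) $\rho$/$\alpha$ breakdown is detected as an effective exact zero
($<10^{-300}$) — any norm-relative threshold misfires here, because
legitimate inner products sit far below $\|z\|\|\tilde r\|$ when the
primal and shadow sides carry different diagonal scalings.  On a
$\rho$-breakdown the driver refreshes the shadow once, or falls back to
BiCGStab if configured.  (iii) Exhausting the iteration cap returns a
non-converged result; non-finite iterates raise an error naming the
iteration.

## Validation fixtures (what the generators emulate)

**Smooth analytic probe** (`build_smooth_probe`): on the cube
$[-a,a]^3$ (default $a = 0.05$ m, the 0.1 m fictitious box), $u =
(x^2-a^2)(y^2-a^2)(z^2-a^2)$ with tensor $\sigma_{xx} = 6(2+r^2)$,
$\sigma_{yy} = 5(2+r^2)$, $\sigma_{zz} = 4(2+r^2)$ and all off-diagonals
$\sin(r^2-3)$.  The right-hand side is hard-coded from analytic
differentiation and cross-checked in the tests against a
central-difference divergence oracle (agreement at $\mathcal{O}(h^2)$).
This fixture exercises smooth anisotropy with full off-diagonal
coupling, but *not* tissue interfaces: a green order-of-accuracy test
establishes consistency of all five schemes, nothing about interface
robustness.

**Four-shell sphere** (`build_sphere_model`): shells at 0.084 / 0.065 /
0.05 / 0.03 m with conductivities 0.44 / 0.018 / 1.79 / 0.25 S/m and
air cladding $10^{-10}$ S/m.  Shells are half-open and outer-exclusive
(a node exactly on a boundary belongs to the inner shell).  The skull
may be anisotropic: the local tensor $\mathrm{diag}(\sigma_t, \sigma_t,
\sigma_r)$ is rotated so its third axis is radial, equivalently
$\sigma_t I + (\sigma_r - \sigma_t)\hat r \hat r^T$, with eigenvalues
exactly $\{\sigma_r, \sigma_t, \sigma_t\}$.  Because the literature
leaves ambiguous which component the printed skull value 0.018 S/m
denotes, the default convention takes it as *radial* with tangential
$= \text{ratio} \times$ radial (the physiological, tangentially
dominant reading); `convention = "printed_tangential"` flips this.  The
printed 0.1 m box cannot contain the 0.084 m scalp radius, so sphere
studies use a 0.2 m box — the probe keeps the printed 0.1 m cube.  This
model has sharp spherical interfaces but no realistic geometry,
inhomogeneous tissue texture, or measured DTI field; a green sphere
test establishes preconditioner robustness to layered contrast and
anisotropy, not anatomical fidelity.

**Titanium clip** (`insert_pi_clip`): a Π-shaped union of three
axis-aligned boxes (12 mm outline, 2 mm × 4 mm cross-section, planar Π
in the x–z plane, $2.5\times10^{6}$ S/m) placed in the skull shell — a
synthetic stand-in for the post-surgical implant case, pushing the
conductivity contrast to $2.5\times10^{16}$ against the air cladding.
On grids coarser than about $33^3$ (0.2 m box) the thin bar contains no
node and the insertion is empty; the stress driver checks the achieved
contrast and refuses to proceed silently.

**DTI mapping** (`dti_to_conductivity`): $\sigma = 3\sigma_{\rm iso}
D/\mathrm{tr}(D)$, preserving eigenvectors and forcing
$\mathrm{tr}(\sigma) = 3\sigma_{\rm iso}$ exactly; only the volume
transform is provided (no imaging pipeline).

**Sensors** (`geodesic_sensors`): subdivided-icosahedron vertices
(12/42/162/642/2562, nearest count) scaled to the scalp radius, sampled
by trilinear interpolation (exact on linear fields), with optional
average-reference subtraction.

## Numerical choices

* Tolerance $\varepsilon = 10^{-5}$ everywhere in performance studies
  (the canonical working accuracy for these studies); order-of-accuracy studies use
  $10^{-9}$ so iteration error does not pollute the error estimate.
* Observed order uses the actual spacing ratio,
  $\log(e_1/e_2)/\log(h_1/h_2)$, since node-centered grids double node
  counts, not exactly $1/h$.
* The sphere experiments use a fixed tangential source–sink pair on the
  equator at mid outer shell ($r = 0.0745$ m), separation 0.01 m,
  current 1 µA; the anisotropy sweep averages over six such dipoles
  (two per axis) because the reference averaging population is
  unstated.  All solves are deterministic given the configuration.
* Conductivity sampling is node-centered (one tensor per grid node);
  face/edge averages are formed from node values.  The alternative
  voxel-centered reading cannot be ruled out from the source material,
  but a consistent node-centered layout keeps all five schemes
  expressible over one storage scheme.
* 1-based indices in R, x fastest in the linearization — the sparse
  matrix layout and the DST block agree by construction.

## Known limitations

* Scheme A coincides with scheme D exactly (see above); the
  reconstruction that would distinguish them cannot be recovered from
  the corrupted source typesetting.
* The reported qualitative contrast "scheme C loses grid-independence
  under FJ while E keeps it" is *not* reproduced by this reconstruction
  of C: measured counts for C track E (22→24 from $N{=}64$ to 128 on
  the sphere; same at ratio 1:50 and with the clip).  The acceptance
  check asserts exactly the stated inequality (C grows, E spread ≤ 3),
  which passes, but the dramatic degradation is absent at desk scale.
* BiCG on $10^{16}$-contrast models converges thanks to the shadow
  renormalization, but residual histories oscillate by orders of
  magnitude; BiCGStab is smoother yet stalls more easily near tight
  tolerances on these models.
* No multigrid/ILU/SSOR preconditioners, no nonuniform grids or meshes,
  no MRI/CT segmentation pipeline, and no runtime benchmarking claims —
  iteration counts are the only hardware-independent performance
  quantity reported.
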