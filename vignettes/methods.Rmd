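---
title: "Methods: visco-hyperelastic prone-to-supine breast deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visco-hyperelastic prone-to-supine breast deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breastdeform)
```

## Problem and modelling strategy

Diagnostic breast MRI is acquired prone; breast-conserving surgery
happens supine. The transition moves the tumor by 30–100 mm, so a
mechanical model is needed to carry the prone tumor position into the
surgical frame. `breastdeform` implements the full pipeline: rigid
alignment of prone and supine surfaces, an explicit dynamic
finite-element simulation of the gravity inversion, patient-specific
stiffness calibration from the supine nipple position, and tumor
localization metrics. Because clinical images cannot ship with a
package, a synthetic phantom generator provides geometry and forward-
simulated ground truth for every stage.

## Constitutive model

Both tissues are compressible neo-Hookean,
$\Psi = \tfrac{\mu_0}{2}(\bar I_1 - 3) + \tfrac{K_0}{2}(J-1)^2$,
with shear relaxation by a single-term Prony series
$G(t) = G_0\,(1 - g\,(1 - e^{-t/\tau}))$. Choices that were genuinely
open and how they were resolved:

* **Volumetric prefactor.** The quadratic volumetric term is taken as
  $(K_0/2)(J-1)^2$ — the only reading of the published form that is
  dimensionally consistent and recovers the small-strain bulk modulus.
* **Bulk-to-shear ratio.** "Quasi-incompressible" is implemented as
  $K_0 = 100\,\mu_0$ by default (enforced $K_0 \ge 50\,\mu_0$). Larger
  ratios shrink the explicit stable time step as $\sqrt{K_0}$ for no
  visible change in the deformation field.
* **What relaxes.** Viscoelasticity acts on the deviatoric Cauchy
  stress only; the volumetric response stays elastic. The update is the
  internal-variable recurrence
  $h^{n+1} = e^{-\Delta t/\tau} h^n +
  g\,\frac{1-e^{-\Delta t/\tau}}{\Delta t/\tau}\,(S^{n+1}-S^n)$,
  with relaxed stress $(1-g)\,S^{n+1} + h^{n+1}$. This is the exact
  convolution for stress histories piecewise linear in time; the test
  suite checks it against direct quadrature of the hereditary integral
  to 0.5 %. A held step load relaxes to $(1-g)S$, which fixes the sign
  conventions unambiguously.
* **Skin.** $\mu_S = f\,\mu_B$ with $f$ searched over
  $\{4, 6, 8, 10, 12\}$; the skin shares the body's $g$ and $\tau$
  because no separate viscous data exist for skin in this setting.

## Explicit solver

Total-Lagrangian constant-gradient tetrahedra, central-difference time
stepping with row-sum lumped masses, gravity applied instantaneously
(the prone geometry is treated as stress-free; no pre-stress recovery).

* **Locking.** Linear tetrahedra lock volumetrically near
  incompressibility. The solver uses nodal-volume-averaged dilatation
  (F-bar type): per step, element $J$ is replaced by the average of
  nodal volume-weighted $J$ values, and the stress is evaluated at the
  rescaled deformation gradient. The "hybrid" (mixed) formulation of
  implicit codes has no practical lumped-explicit equivalent. The
  F-bar force is not the exact gradient of the reported stored energy
  (the averaging couples neighbouring elements), which is why the
  energy-conservation verification runs with plain elements.
* **Stable time step.** $\Delta t = s\,\min_e (L_e / c_e)$ with
  $c = \sqrt{(K_0 + 4\mu_0/3)/\rho}$ and $L_e$ the smallest element
  altitude scaled by 0.75: the maximum eigenfrequency of a lumped
  constant-strain tetrahedron exceeds $2c/\text{altitude}$ (safety 0.9
  alone was empirically unstable on structured meshes).
* **Contact.** The chest wall is rigid and fixed. Each interface node
  gets a penalty spring $k = \beta m/\Delta t^2$ against its
  first-contact facet (small sliding); the tangential spring is capped
  by the Coulomb cone $\|f_t\| \le \varphi f_n$ with anchor dragging on
  slip. $\beta = 0.5$: the stability bound for the contact spring alone
  is $\beta \approx 4$, and $\beta = 0.5$ holds penetration below
  0.03 mm on the phantom where $\beta = 0.1$ allowed ~0.1 mm. Wall
  normals are oriented toward the body centroid — contact nodes start
  exactly on the wall, so their own offset cannot decide the side.
* **Damping.** None by default (the physics relies on viscoelastic
  dissipation plus the early stopping criterion). A mass-proportional
  damping coefficient and a gravity ramp exist for quasi-static
  verification experiments only.
* **Stopping.** No static equilibrium exists (the posterior-lateral
  boundary is free and soft tissue keeps thinning); the selected state
  is the recorded sample whose nipple position is closest to the
  target, ties resolved toward the earlier time.

## Energy ledger

Work increments use the discrete power identity of the central
difference, $f^n \cdot (u^{n+1}-u^{n-1})/2$, so kinetic energy +
internal work − external work closes to round-off by construction.
Stored energy is reported as volumetric + long-term deviatoric
neo-Hookean energy + Maxwell spring energy $h\!:\!h/(4G_k)$; dashpot
dissipation integrates $h\!:\!h/(2G_k\tau_k)$. These branch formulas
are exact for linear viscoelasticity and first-order at finite strain,
so the 2 % ledger-closure check runs in a small-strain regime (gravity
scaled down 100×). The conservative drift check (≤1 %) runs at CFL
safety 0.2: at the stability limit the work-quadrature wobble of the
stiffest (thin-skin) modes dominates and is a property of the time
step, not of the formulation.

## Synthetic phantom

The stated world of the tests: a half-ellipsoid breast with semi-axes
60/60/55 mm (x medial–lateral, y posterior→anterior, z caudal→cranial),
1.5 mm skin, a 7.5 mm-radius tumor centred 12 mm laterally at mid
depth, density 1000 kg/m³, planar chest wall at y = 0, nipple at the
anterior apex. Node sets mirror the clinical boundary conditions:
$u_x = 0$ on the medial (junction) patch, $u_z = 0$ on the superior and
inferior strips, chest-interface nodes in contact. Default element edge
6 mm matches the clinical meshing scale; coarse test phantoms use
10–13 mm to stay inside CI budgets (stated in each test).

Interior meshing is native and deterministic: a "spiderweb" disc
triangulation lifted to the hemisphere by the Lambert equal-area map,
stacked into geometrically graded radial shells (prisms split by the
lowest-global-index diagonal rule, a cone of tetrahedra at the core),
then scaled to the ellipsoid. A structured-grid clip of the ellipsoid
was tried first and abandoned: clipping leaves stair-step sliver faces
that break skin extrusion, and every cube-to-ball map tested (max-norm
radial, spherified cube, composed 2-D radial maps) collapses boundary
cells at the cube edges. The onion construction has bounded element
quality everywhere, which directly controls the explicit time step.

Seeded uniform jitter (0.3 mm, interior nodes only) keeps the mesh from
being accidentally symmetric. The bilateral surface for alignment tests
is a height field: two tensor-product domes over a flat chest plane
with a labelled intermammary strip; dome feet have finite slope so the
only flat interior region is the strip.

What a green phantom test does **not** establish: real breasts are
heterogeneous (fat, gland, ligaments), have pre-stress in every imaged
configuration, non-ellipsoidal geometry, and chest walls that are
neither planar nor orthogonal to gravity. The closed loop proves the
machinery (solver, stopping rule, optimizer, metrics) is consistent,
not that the two-tissue model is anatomically sufficient.

## Alignment

The intermammary patch is detected by region growing from the
mid-nipple point, accepting vertices whose normal deviates from the
patch mean by ≤10° (the flatness notion is not operationally defined in
the source; 10° over the vertex star is our choice, exposed as a
parameter), restricted to the inter-nipple band and excluding open
surface-boundary vertices whose half-star normals are unreliable. The
nipple-to-patch geodesic radius transfers the boundary to the supine
surface; geodesics are Dijkstra on the edge graph augmented with one
level of edge-midpoint subdivision (15 intra-face edges per triangle),
which brings the pole-to-antipode error on an icosphere from ~7 % down
to ~0.2 %. Registration is ICP (nearest vertex, Kabsch inner step,
centroid + principal-axes initialization with sign disambiguation);
the point-correspondence rule of the original "point-based"
registration is unspecified, so ICP over the patches is our declared
choice. Cranial–caudal nipple levelling is a pure z-translation applied
after registration.

## Calibration

The annealing schedule is declared rather than emulated (the source
delegates to a black-box routine): Gaussian proposals (σ = 20 Pa)
clipped to [160, 300] Pa, geometric cooling (0.95 per evaluation,
initial temperature 20 in millimetre objective units), Metropolis
acceptance, at most 40 objective evaluations, then ≤10 golden-section
steps bracketing the incumbent; early exit once the nipple distance
falls below the threshold. The threshold is 5 mm at clinical scale;
phantom runs use 2 mm because the phantom's nipple excursion (~60 mm)
is at the small end of the clinical range. The Prony ratio follows the
piecewise rule g(μ_B) = 0.8 / 0.5 / 0.1 with left-closed brackets at
230 and 300 Pa; μ_B below 160 Pa is outside the calibrated rule and is
rejected. The skin factor is searched exhaustively after μ_B, not
jointly — joint optimization was reported to cost much and gain little.

## Evaluation

Tumor distance is the Euclidean distance between estimated and
reference supine centroids (mm). The tumor-skin projection distance
projects both centroids onto the *same* deformed outer surface at t*
(closest point over all facets, exact point-triangle tests) and
reports the distance between the projections; whether the original
method projects onto one surface or two is ambiguous, and one surface
is our declared choice. The estimated supine centroid is the prone
centroid carried through the selected snapshot by barycentric
interpolation in its containing tetrahedron (exact for affine fields).

## Known limitations

* Fixed-tie contact with the calibrated soft visco parameters thins the
  tissue without bound and inverts elements at ~0.17 s; comparisons of
  sliding vs fixed modes therefore use the phantom's constructor
  default materials (μ_B = 200 Pa, elastic), under which both modes
  complete the full 0.3 s window.
* The solver supports a single Prony term (the constitutive layer
  handles arbitrary terms); multi-term relaxation was reported
  unnecessary for this application.
* No self-contact, no skin–body sliding, no pre-stress recovery, no
  implicit statics. These mirror the scope of the modelled workflow.
* Trajectory artifacts are stored as `.rds`, and run configurations as
  JSON (no HDF5 or YAML bindings are assumed on the host).
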