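# breastdeform

Patient-specific simulation of prone-to-supine breast deformation for
surgical planning.

Breast-conserving surgery is performed supine, while the diagnostic MRI
that localizes the tumor is acquired prone. The positional change
deforms the breast by several centimetres, so the prone tumor position
cannot be used directly in the operating room. `breastdeform` models the
breast as a visco-hyperelastic solid, simulates the prone-to-supine
transition by inverting gravity in an explicit dynamic finite-element
solver, calibrates the tissue stiffness patient-specifically from a
single surface landmark (the supine nipple position), and maps the
prone tumor centroid into the supine frame.

## The model

Two tissues (breast body, skin shell) share a compressible neo-Hookean
strain energy

    Psi = mu0/2 (I1bar - 3) + K0/2 (J - 1)^2,

with `mu0` the initial shear modulus, `K0 >> mu0` the bulk modulus
(quasi-incompressible, default `K0 = 100 mu0`), `I1bar` the first
isochoric invariant and `J = det F`. Shear stress relaxes through a
single-term Prony series,

    G(t) = G0 (1 - g (1 - exp(-t / tau))),   tau = 0.01 s,

advanced by an internal-variable recurrence that is exact for
piecewise-linear stress histories. The skin shear modulus is tied to
the body by a factor `f`: `mu_S = f mu_B`. Dynamics are total-Lagrangian
explicit (central difference, lumped mass) on linear tetrahedra with
nodal-averaged dilatation against volumetric locking; the rigid chest
wall acts through penalty contact with Coulomb friction (`phi = 0.5`)
in a small-sliding formulation. Because the posterior-lateral boundary
is unconstrained, no static equilibrium exists; the simulation state is
selected by the nipple stopping criterion — the sample whose simulated
nipple is closest to the observed supine nipple.

Calibration solves

    argmin_{mu_B in [160, 300] Pa}  | r_nipple_est(mu_B) - r_nipple |

by bounded simulated annealing with golden-section refinement, with the
Prony ratio tied to stiffness (g = 0.8 on [160, 230) Pa, 0.5 on
[230, 300) Pa, 0.1 above) and an exhaustive search over
`f in {4, 6, 8, 10, 12}` afterwards.

Everything downstream is exercised on synthetic phantoms: a
half-ellipsoid breast (60/60/55 mm semi-axes) with a 1.5 mm extruded
skin shell, a 7.5 mm tumor inclusion, a planar chest wall and labelled
boundary node sets, plus a forward-simulated "supine" ground truth with
known material parameters, so the whole pipeline closes the loop
without patient data.

## Worked example

```r
library(breastdeform)

spec  <- phantom_spec(edge = 12e-3, seed = 1)   # coarse phantom, ~3k tets
model <- make_breast_phantom(spec)
sim   <- simulation_config()                     # gravity (0, -9.8, 0), 0.3 s

# forward-simulate a supine "ground truth" at known stiffness
truth <- make_supine_truth(model, mu_B = 220, f = 6, config = sim,
                           sample_time = 0.16)

# recover the stiffness from the supine nipple alone
cfg <- calibration_config(stop_threshold = 2e-3, seed = 1)
res <- calibrate(model, truth$nipple, config = cfg, sim_config = sim)
print(res)
#> calibration_result: mu_B = 217.5 Pa (g_B = 0.8), f = 6
#>   nipple distance 0.15 mm at t* = 0.160 s (6 evaluations, seed 1)

rep <- evaluate_supine(model,
                       list(displacement = res$displacement,
                            t_star = res$t_star,
                            nipple_distance = res$distance),
                       reference_tumor = truth$tumor_centroid,
                       target_nipple = truth$nipple)
print(rep)
#> evaluation_report: tumor distance 0.11 mm, tumor-skin projection 0.05 mm
#>   nipple residual 0.15 mm at t* = 0.160 s
```

The true modulus (220 Pa) is recovered within a few Pa from six
finite-element runs, and the tumor carried through the calibrated
displacement field lands within ~0.1 mm of the ground-truth supine
centroid. `run_pipeline(default_run_config())` chains the same stages
end to end and writes STL surfaces, Slicer `.mrk.json` nipples and JSON
reports, mirroring the artifact formats used for real cases.

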