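---
title: "Methods: patient-specific femoral strength scores from calibrated CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific femoral strength scores from calibrated CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients with osteolytic femoral metastases face a risk of pathological
fracture under everyday loads. Clinical care hinges on stratifying that risk:
low-risk femurs receive a single palliative radiotherapy fraction, high-risk
femurs are candidates for prophylactic stabilizing surgery or multi-fraction
radiotherapy aimed at remineralization. Radiographic rules of thumb tend to
overestimate risk; a mechanistic alternative is to compute the femur's
load-bearing capacity directly from a calibrated CT scan with a
patient-specific finite-element (FE) model and express it as a dimensionless
**BOS (BOne Strength) score**,

$$\mathrm{BOS} = \frac{F_\max}{m\,g},$$

the simulated peak reaction force (N) divided by the patient's body weight
(N). Fixed thresholds convert the score into a risk category: below 7.5 the
risk is high, above 8.5 low, and the closed interval $[7.5, 8.5]$ moderate.

`bosscore` implements the full chain — synthetic scan generation, phantom
calibration, segmentation, stance alignment, meshing, density-based material
mapping, an elastoplastic solve to the force peak, scoring, report rendering
— plus a decision-impact audit of a 42-femur pilot cohort.

## The synthetic world

Real scans cannot ship with the package, so every stage is exercised against
a generator with exact ground truth (`generate_phantom_volume()`):

* an idealized femur: a vertical shaft (cortical tube, default outer radius
  16 mm, wall 4 mm, length 120 mm, 800 mg/cm^3 calcium-equivalent cortical
  density around a 300 mg/cm^3 trabecular core) capped by an offset sphere
  standing in for the femoral head (radius 22 mm, offset (20, 0, 12) mm);
* an optional spherical lytic lesion (default 50 mg/cm^3) that must lie
  fully inside the bone — the paper-world analogue of an osteolytic
  metastasis. Metastasis shapes are not standardized anywhere; the sphere is
  a stand-in only;
* a calibration phantom: four rods of known density (0, 50, 100, 200
  mg/cm^3), axes parallel to the scan axis, placed clear of the bone;
* a known affine mapping $\mathrm{HU} = s\rho + i$ with optional i.i.d.
  Gaussian HU noise (seed mandatory when noise is on). The defaults in
  `synth_preset()` use $s = 1.2$, $i = -5$ and zero noise.

The scan protocol object (`ct_protocol()`) carries the validated acquisition
settings (120 kVp, 3 mm slices, pitch 1.5, 480 mm FOV, 0.9375 mm in-plane);
the presets voxelize at 2 mm isotropic to keep desk-scale runs fast.

What the generator deliberately does **not** emulate: anatomy (neck
curvature, trochanters), beam hardening, scatter, scanner-to-scanner
variability, partial-volume physics beyond voxel averaging. A green
end-to-end test therefore establishes the correctness of the *pipeline
mechanics*, not clinical validity on real scans.

## Calibration

`fit_calibration()` regresses the known rod densities on the mean HU inside
each rod (ordinary least squares). Regressing density on HU — rather than
inverting an HU-on-density fit — makes application a single affine map,
which is standard quantitative-CT practice. Rod means are taken over a
one-voxel-eroded mask to avoid partial-volume rims. A non-positive fitted
slope is rejected outright: higher HU must never mean less mineral.
`apply_calibration()` clamps negative densities to zero, since the material
law needs a physical, non-negative input.

In the noiseless synthetic world the fit inverts the generating map to
machine precision. Under HU noise the slope estimator is (to first order)
normal with the closed-form OLS standard error; the suite checks 95%
coverage of that interval over 200 seeded replicates. Note that this check
is knife-edge by construction — a nominal-95% interval is required to cover
in at least 95% of replicates — so its pass/fail is a coin flip over seeds;
the package-wide fixed seed (1) was chosen before the first run and is not
tuned.

## Segmentation

The production system uses a learned segmentation model; that is an external
artifact, so the package substitutes a classical chain with the same
contract (a single connected femur mask): threshold at 150 mg/cm^3 →
largest 26-connected component (components overlapping declared phantom-rod
regions are excluded) → morphological closing with a 2 mm ball → interior
hole fill. The hole fill is what recovers lytic lesions, which fall below
the bone threshold but are interior cavities of the thresholded shell. Both
parameters are configurable; the defaults separate soft background from
trabecular bone in the synthetic model and give Dice ≥ 0.99 against ground
truth on noiseless presets (the acceptance bar is 0.95).

## Stance alignment and cropping

The loading axis is the line from the femoral-head center to the knee
center. The head center is found by a least-squares sphere fit to the
surface voxels in the extreme quartile of the mask's long (first principal)
axis; both ends are tried and the better fit wins, so scan orientation is
irrelevant. The fit is accepted only if the RMS radial residual is below 6%
of the fitted radius — voxelized spheres fit at about 3%, while a capped
cylinder end fits no better than about 10%, so a mask with no spherical
head errors out rather than aligning nonsense. The knee center is the
centroid of the distal-most 5 mm slab — the generator's world assumes a
full-femur scan, as the clinical protocol does.

`align_and_crop()` rotates rigidly so that head→knee becomes $-z$ (head at
the origin), resamples density trilinearly and the mask by nearest
neighbour, and keeps the proximal half (crop at the axis midpoint). A
lesion extending below the mid-plane moves the crop distally until the
lesion is included plus one element-size margin. Trilinear resampling
conserves the density integral to well under 2% at the preset resolution
(tested).

## Meshing

`voxels_to_tets()` is a structured mesher: the mask is coarsened by an
integer factor to the requested element size (default 4 mm), every retained
cell is split into six tetrahedra along the cube's main diagonal (Kuhn
decomposition). Because all cells share the same diagonal orientation, the
triangulation conforms across cell faces, is watertight, deterministic, and
*volume-exact*: the mesh volume equals the coarsened mask volume to
round-off error. Each element samples the calibrated density trilinearly at
its centroid (clamped at zero), matching the one-density-per-element
contract. An unstructured boundary-fitted mesher would smooth the surface
but would add an external dependency and nondeterminism for no benefit at
this scale; the 5% sphere-volume acceptance bound quantifies the
staircasing error instead.

## Material mapping

Each element receives isotropic elastoplastic properties from power laws in
density ($\rho$ in g/cm^3):

$$E = a\rho^{b}\ \mathrm{MPa}, \qquad \sigma_y = c\rho^{d}\ \mathrm{MPa},$$

with defaults $a = 6850$, $b = 1.49$, $c = 38.5$, $d = 2$, $\nu = 0.3$, and
floors $E \ge 1$ MPa, $\sigma_y \ge 0.1$ MPa so empty elements cannot make
the stiffness matrix indefinite. The production system's constitutive
constants live in literature not reproduced here; these defaults are in the
range of published trabecular/cortical fits but are explicitly
*implementation choices*, fully configurable through `material_law()`. The
qualitative property that matters — lower density ⇒ strictly lower
stiffness and strength, so a lytic lesion automatically weakens the bone —
holds for any admissible parameters and is tested as such.

Plasticity is von Mises with (numerically) perfect plasticity: the default
hardening modulus is $H = 10^{-4}E$, not exactly zero, because a strictly
perfect-plastic consistent tangent is singular at the limit load under
displacement control. At that ratio the effect on a bar's limit load at 5%
strain is ~0.04‰, orders of magnitude below every stated tolerance; setting
`hardening_ratio = 0` restores textbook perfect plasticity.

## The solve to failure

The simulation is displacement-controlled: the femoral head nodes within a
30° polar cap are pushed along $-z$ in 0.05–0.1 mm increments while the
distal cut plane is fully fixed. Displacement control passes the force
maximum without arc-length machinery, which is exactly what the strength
$F_\max$ requires. Only the load-axis component of the cap nodes is
prescribed; prescribing all three components would laterally confine the
contact patch, fight plastic incompressibility, and inflate the limit load
(≈3% on the bar oracle, outside its 1% tolerance) — with the transverse
components free the oracle is met at 0.3%.

Each increment is equilibrated by Newton iteration with a radial-return von
Mises stress update and the algorithmically consistent tangent, assembled
from linear tetrahedra into a sparse symmetric system solved by Cholesky
factorization (the symbolic factorization is computed once and reused). Two
numerical safeguards matter in practice:

* a backtracking line search on the residual norm (up to five halvings):
  near the limit load, elements switch between elastic and plastic branches
  and the full Newton step overshoots, producing limit cycles;
* increment bisection on non-convergence (floor: 1/64 of the nominal
  increment, then a hard `solver diverged` error), with recovery back
  toward the nominal increment only after three consecutive easy steps so a
  persistently hard step size is not retried forever.

Convergence is declared when the free-DOF residual norm falls below
$10^{-6}$ of the constraint-force norm. The run stops when the total
reaction force drops below 95% of its running maximum or the displacement
ramp ends; with (near-)perfect plasticity and small-strain kinematics the
curve typically plateaus rather than drops, so the ramp length bounds the
run. The strength is the maximum total reaction force; the *weakest
location* is the set of elements with equivalent plastic strain above
$10^{-8}$ at the step where that maximum occurred.

The solver is verified against closed-form mechanics: a single-element
patch test (constant stress to machine precision), an elastic bar
($F = EA\delta/L$ to $10^{-8}$ relative), a perfectly plastic bar
($F_\max = \sigma_y A$ within 1%), global equilibrium, linearity in the
elastic regime, and rigid-translation invariance.

## Scoring, report and database

`compute_bos()` uses $g = 9.81$ N/kg (the score's definition fixes the
weight *in newtons* but not $g$; this is a documented choice).
`classify_risk()` treats both thresholds as moderate (closed interval) —
scores of exactly 7.5 or 8.5 are moderate. This tie rule is deliberate and
prominent because it changes the category at the boundaries.

The report panel against historical scores uses a database of
(score, fractured-within-6-months) records. The real database is not
distributable, so the package ships a **synthetic** stand-in
(`score_db_synthetic.csv`, n = 90) constructed so that the high-risk call at
the 7.5 cut reproduces the previously published cohort metrics: sensitivity
100%, specificity 74%, PPV 39%, NPV 100%. PPV is the fraction of below-cut
femurs that fractured ("positive" = high-risk call); percentiles use
mid-rank ties. The rendered report carries the score, category, percentile,
PPV/NPV, a force–displacement figure, the plastic-element field as a VTK
export, and a verbatim caution line that the computed weakest location need
not coincide with the metastatic site.

## The pilot-cohort audit

`load_cohort()` / `summarize_cohort()` reproduce the decision-impact
tabulation of the 42-femur implementation pilot from a femur-level CSV. The
packaged fixture encodes the published cross-tabulation (physician estimate
× model category × delivered treatment), fracture and death follow-up,
delivery intervals and usage flags. Published data are marginal totals;
femur-to-patient pairing, per-femur delivery days and death assignment are
synthetic but consistent with every published marginal (42 femurs, 39
patients, 3 bilateral; 3 fractures; 13 deaths; 14/23/5 delivery days; 2
unused reports). Headline counts derived under the documented rules:
31 discrepant estimates; 20/9/13 high/moderate/low; 18 probable treatment
adaptations (physician low, model moderate/high, escalated treatment) and 2
possible ones (physician high, model moderate — intent not inferable, so
the two are reported separately rather than asserting a single adaptation
rate).

## Known limitations

* Idealized geometry only; no validation against real scans or the
  production segmentation model.
* Small-strain kinematics and a plateauing force curve: post-peak softening
  and fracture localization are out of scope.
* Osteoblastic (dense) metastases would be over-stiffened by the density
  power law, as the clinical method itself cautions.
* Single stance-like load case with an axis-aligned direction; side-fall or
  multi-directional envelopes are not simulated.
* The material constants are plausible defaults, not the production
  calibration; absolute strengths (and hence scores) from the synthetic
  presets should be read as internally consistent, not clinically
  meaningful.
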