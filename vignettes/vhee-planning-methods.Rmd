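---
title: "Methods: VHEE spot-scanning treatment planning in vheetps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VHEE spot-scanning treatment planning in vheetps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`vheetps` implements a research treatment-planning chain for very
high-energy electron (VHEE, > 50 MeV) spot scanning: beam base data,
synthetic voxel phantoms, beam's-eye-view (BEV) spot placement,
water-equivalent ray tracing, a pencil-beam influence matrix, non-negative
fluence-map optimisation, prescription normalisation, DVH metrics, and an
automated sweep over beam number, energy and spot spacing. Each field
carries a *single energy layer*: unlike protons, VHEE depth-dose curves
have no Bragg peak to stack, so longitudinal shaping comes entirely from
crossfiring weighted fields.

Everything is deterministic. Seeds are accepted throughout and echoed into
records for provenance, but no stage draws random numbers.

# Beam base data

The dose engine consumes, per energy `E` and initial spot size `sigma0`,
two tables on a common depth lattice (default 1 mm step to 350 mm):

* the integrated depth dose `IDD(z)`, max-normalised to 1, and
* the scattering spread `sigma_scatter(z)` in water.

These would normally come from Monte-Carlo water-phantom simulations.
Monte-Carlo transport is out of scope here, so the package provides both a
**tabulated import** (CSV `depth_mm,idd,sigma_scatter_mm` plus a JSON
metadata sidecar) and a documented **analytic generator**:

* `IDD(z) ∝ (1 − exp(−z/z_b(E))) · exp(−μ(E) z)` — a build-up term (dose
  builds over `z_b` as the secondary-electron field equilibrates) times a
  quasi-exponential fall-off. `z_b(E) = 30 mm · (E/100 MeV)` is
  non-decreasing and `μ(E) = 0.004 mm⁻¹ · (100 MeV/E)` strictly decreasing
  in energy, so higher energies keep a larger fraction of the maximum dose
  at depth — the defining VHEE plateau behaviour.
* `sigma_scatter²(z) = ∫₀ᶻ T(z′) (z − z′)² dz′` — the Fermi–Eyges second
  moment with Highland scattering power `T(z) = (14.1 MeV / E(z))² / X₀`,
  `X₀ = 360.8 mm` (water), and the depth-local mean energy
  `E(z) = max(E₀ − S·z, 1 MeV)` from a constant collisional stopping power
  `S = 0.2 MeV/mm`. The Highland log-correction is omitted; with it, the
  ordering and magnitudes relevant here do not change. The moment integral
  is evaluated as `z²I₀ − 2zI₁ + I₂` with cumulative trapezoids on a
  10×-refined lattice (keeping quadrature error well below the 0.5 %
  oracle band used in the tests).

The total spot width combines the independent in-air and in-medium
spreads in quadrature, `sigma_tot² = sigma0² + sigma_scatter²(z)` — the
standard convolution of independent Gaussian kernels. Table lookups are
piecewise linear; `IDD` is clamped to 0 beyond the table end (distal
fringe), `sigma_scatter` is clamped to its end values. These rules only
affect dose beyond 350 mm of water-equivalent depth.

The defaults reproduce the qualitative beam-property ordering expected of
VHEE: scattering sigma strictly decreasing with energy at fixed depth,
normalised spot growth `sigma_tot/sigma0` shrinking as `sigma0` grows from
2 to 42 mm, and `FWHM = 2√(2 ln 2)·sigma` (42 mm sigma ≈ 10 cm FWHM).

# Phantoms

`make_phantom()` builds voxel phantoms (relative-to-water density plus
boolean structure masks) on an isotropic grid, default 2 mm — the dose
grid used throughout. Recipes:

* `water_box` — uniform water, centred cuboid PTV; the reference medium
  for conservation and symmetry tests.
* `pelvis` — elliptic body cylinder (semi-axes 150 × 100 mm), ellipsoidal
  prostate-like PTV (~79 cm³) centred at 100 mm depth below the anterior
  surface, with abutting posterior "rectum" and anterior "bladder" tubes.
* `thorax_midline` / `thorax_chestwall` — elliptic body with two
  low-density lung cylinders (relative density 0.3, a typical clinical
  value), heart, oesophagus and spinal-cord surrogates; a spherical
  ITV-analogue target either midline (overlapping the heart projection)
  or against the left chest wall. Target volumes are calibrated to the
  cohort medians 206.7 and 271.5 cm³ by taking the `k` nearest voxel
  centres to the target centre with `k = round(V/voxel volume)` — a
  digital ball whose voxelised volume matches by construction (observed:
  within 0.4 %, the residual coming from distance ties on the lattice).

Axes: x right→left, y anterior→posterior, z inferior→superior; origin at
the grid corner; masks are voxel-centre membership; air outside the body
has density 0.001. Phantom stores are NRRD (ASCII encoding) with a JSON
manifest; NRRD was chosen as the simplest spacing-aware standard format,
DICOM deliberately excluded.

What the phantoms do **not** emulate: real anatomical variability, bone,
HU calibration, motion. A green end-to-end test therefore establishes that
the planning chain behaves correctly and reproduces the *direction* of
parameter trends on controlled geometry — not any patient-cohort effect
size.

# Beam geometry and spot placement

Beams are coplanar and parallel (infinite SAD), appropriate for
magnetically scanned pencil beams; a finite source distance is a
configurable extension hook, off by default. Gantry 0° enters anteriorly
travelling +y; angles increase toward patient-left entry, giving beam axis
`(−sin g, cos g, 0)` and BEV basis `u = (cos g, sin g, 0)`,
`v = (0, 0, 1)`.

`arrange_beams(n, span, center)` places `n` equidistant angles: endpoint
inclusive with pitch `span/(n−1)` for partial arcs (the 200° lung-style
arc), pitch `360/n` without a duplicate endpoint for full rings (the 360°
prostate-style ring). The arc centre is a required configuration
parameter, default 0° (anterior).

Spots live on a square lattice of pitch `k · sigma0` (k conventionally
1.0–3.0; the multiple refers to the *initial* sigma) anchored at the
centroid of the target's BEV footprint. The footprint is the orthographic
projection of mask voxel centres, rasterised at the grid resolution. A
lattice point is kept iff it lies inside the footprint dilated by the
margin (default 5 mm), measured as **Chebyshev** (square-kernel) distance
to the nearest footprint cell centre, boundary points kept. The square
kernel was chosen over a Euclidean one deliberately: it makes the
enumerate-and-filter count on a rectangular footprint exact (a 40 × 40 mm
footprint with 5 mm margin and 6 mm pitch keeps 9 × 9 = 81 spots,
`|k·6| ≤ 25` per axis) and it guarantees the coverage property — whenever
`spacing ≤ 2·margin`, every footprint cell lies within
`spacing·√2/2` of a kept spot.

Radiological depth is the line integral of relative density from the grid
boundary to each voxel centre along the beam axis, computed by exact
Siddon/Amanatides–Woo voxel traversal (air contributes its near-zero
density; with unit density the map equals geometric depth exactly).

# Pencil-beam dose engine

Dose per unit spot weight at voxel `i` is the product of longitudinal and
lateral factors, evaluated at the voxel's radiological depth `d_i`:

```
D_i = IDD(d_i) · exp(−r_i² / (2 σ_tot(d_i)²)) / (2π σ_tot(d_i)²)
```

with `r_i` the lateral distance from the pencil axis in the BEV plane.
Choices the underlying algorithm leaves open, fixed here:

* The lateral Gaussian is normalised to unit integral over the lateral
  plane (units mm⁻²), so the IDD carries all longitudinal information.
  This makes per-slice lateral mass conservation a testable invariant
  (each water slice integrates to `IDD(z)` within the cut-off tolerance).
* Lateral cut-off at `3.5 σ_tot` (≥ 99.8 % of kernel mass), configurable;
  entries beyond it are exactly zero, bounding influence-matrix sparsity.
* Dose-to-water heterogeneity handling: both the IDD lookup and
  `σ_tot` use radiological depth; lateral heterogeneity within the kernel
  is ignored. This is the standard analytic pencil-beam compromise and the
  reason results in strongly heterogeneous media (lung, air cavities)
  should be treated with caution.
* Influence entries are in arbitrary dose units; absolute calibration is
  deferred to prescription normalisation (every reported plan has target
  mean = 100 % of prescription), so no machine-specific output factor is
  claimed.

The influence matrix stacks one sparse column per spot (field-major, each
field's lattice in row-major v-then-u order); total dose is the
matrix–vector product with the weight vector. The compiled kernel and the
R-level interpolation use identical arithmetic, which is what allows the
brute-force per-voxel oracle test to demand 1e-12 relative agreement.

# Optimisation

The objective is a weighted sum of quadratic penalties (standard inverse
planning forms; the underlying goals name clinical intent, not formulas):

* uniform target: `p · mean((D_i − d_ref)²)` over the target (exactly one
  per target structure);
* max dose: `p · mean(max(D_i − d_ref, 0)²)`;
* mean dose: `p · (mean(D) − d_ref)²`;
* DVH-max: overdose penalty restricted to the violating hottest fraction —
  the allowed `volume_fraction · n` hottest voxels are exempt, every
  further voxel above `d_ref` is penalised. The violating set is re-sorted
  every evaluation, making this term non-convex; gradients are exact
  almost everywhere.

Solver: L-BFGS-B (projected quasi-Newton, lower bound 0) from uniform
positive initial weights (all 1), stopping on projected-gradient tolerance
(`pgtol`, default 1e-8) or `max_iter` (default 500). The solver is
deterministic; the reported trace is the sequence of improving
("accepted") function evaluations, which is non-increasing by
construction — L-BFGS-B line searches may probe non-improving points,
which are not iterates. Hitting `max_iter` without the gradient test is
recorded as `converged = FALSE`; such plans are retained as recorded
outcomes (a non-viable configuration is itself a result, e.g. very coarse
spot spacings).

Default protocol objective sets (prostate: PTV uniform at 60 Gy with
rectum/bladder mean- and max-dose penalties; lung: ITV uniform at 55 Gy
with lung/heart/oesophagus/cord penalties) are shipped as *editable,
non-authoritative* starting points: the clinical protocols they gesture at
derive constraint values from trial guidelines that are not reproduced
here.

Normalisation rescales weights and dose by
`prescription / mean(target dose)`; afterwards the target mean equals the
prescription exactly, which is why the headline acceptance values (60 Gy
pelvis / 55 Gy thorax target means) are exact post-conditions computed by
the full chain rather than tuned quantities.

# Plan evaluation

Cumulative DVHs and the metric set: `Dx%` uses the descending-sort rank
convention `ceiling(x/100 · n)` (no interpolation — deterministic and
directly checkable against a sorting oracle; interpolated quantiles were
rejected for that reason). `D_vcm³` is the same at rank
`ceiling(v / voxel volume)`; `V_xGy` is the percentage of structure voxels
at or above `x`; the homogeneity index is `(D2% − D98%) / D50%` (ICRU-83
style, lower = more homogeneous; the convention is isolated behind one
function since competing definitions exist).

# Sweep pipeline

`run_sweep()` executes the Cartesian product of phantom × beam count ×
energy × spacing, each plan running the full chain with a per-plan derived
seed, and emits a long/tidy record table (one row per structure × metric,
plus plan-level rows for spot count, spots per 100 cm³ of target, and
convergence). Failures are logged rows, not fatal errors. A
`pseudo_reference()` 12-beam, 360° plan is provided for self-contained
difference tables; it is explicitly **not** a clinical VMAT reference.
Difference conventions: `diff = plan − reference`,
`rel = 100·(plan − reference)/reference`.

Configs are JSON (the environment's guaranteed R stack has no YAML
reader); the schema mirrors the field list above. Influence matrices
export to MatrixMarket + JSON sidecar for the same reason (no HDF5
binding guaranteed).

# Numerical and testing notes

* Tolerances: engine-vs-oracle 1e-12 relative (identical arithmetic);
  WEPL vs 0.1 mm dense marching 0.5 mm; Fermi–Eyges vs adaptive
  quadrature 0.5 %; lateral mass conservation 1 % (cut-off mass is
  99.78 %); optimiser finite-difference gradient 1e-4; dose recovery
  0.5 % RMS.
* End-to-end trend suites (spacing 1.0→3.0 σ degrades D95 and HI;
  additional beams reduce OAR mean dose) run on 3 mm desk-scale phantoms
  to keep the suite inside its time budget; the acceptance-target checks
  use the default 2 mm phantoms.
* Degenerate inputs fail loudly: empty footprints/structures, targets
  receiving no influence, non-monotone base-data tables, misaligned
  masks, negative weights.

# Known limitations

Analytic base data stands in for Monte-Carlo transport (no angular/energy
spread in air, no treatment-head contamination, no nuclear or
bremsstrahlung secondaries); dose is dose-to-water on a parallel-beam
geometry; optimisation is unconstrained-penalty (no hard constraints,
robust/4D, mixed-energy or beam-angle optimisation); no DICOM-RT, no
biological indices, no FLASH dose-rate modelling. Cohort-level clinical
effect sizes require patient data and are represented here only as
direction-of-trend properties on synthetic phantoms.

Not every clinical trend survives the transfer to an idealised phantom:
on the cylindrically symmetric pelvis recipe the *rectal* mean dose falls
monotonically as beams are added (the trend the test suite asserts), but
the *bladder* mean dose rises — with a full ring of beams centred
anteriorly, adding beams sends proportionally more fluence through the
anterior tube that abuts the PTV. Clinical bladder sparing with more
beams is a statement about patient anatomy and a VMAT comparator, neither
of which this phantom represents; treat phantom OAR numbers as chain
diagnostics, not clinical predictions.
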