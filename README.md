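# vheetps

Spot-scanning treatment planning for very high-energy electron (VHEE)
beams, in R.

VHEE beams (> 50 MeV electrons) are an emerging external radiotherapy
modality: they penetrate to deep-seated targets with an extended
depth-dose plateau, can be steered magnetically for spot scanning, and —
because there is no Bragg peak — every field is delivered as a *single
energy layer*, with all dose shaping done by crossfiring weighted pencil
beams. Planning studies for this modality need the full inverse-planning
chain long before any clinical machine exists. `vheetps` provides that
chain as a self-contained research toolkit:

* **Beam base data** — per-energy integrated depth dose `IDD(z)` and
  scattering spread `sigma_scatter(z)` in water, either imported from
  tabulated (e.g. Monte-Carlo) data or generated analytically:
  build-up × exponential IDD and the Fermi–Eyges second moment
  `sigma²(z) = ∫₀ᶻ T(z′)(z−z′)² dz′` with Highland scattering power
  `T = (14.1 MeV / E(z))² / X₀`. Spot widths combine in quadrature,
  `sigma_tot² = sigma0² + sigma_scatter(z)²`.
* **Synthetic phantoms** — water box, pelvis (PTV + rectum + bladder) and
  two thorax variants (low-density lungs, heart, oesophagus, spinal cord,
  with midline or chest-wall targets), stored as ASCII NRRD.
* **Geometry** — equidistant coplanar beam arrangements, beam's-eye-view
  projection, square spot lattices with a 5 mm dilated margin, and exact
  Siddon-style water-equivalent ray tracing.
* **Dose engine** — pencil-beam dose-to-water kernel
  `D_i = IDD(d_i) · exp(−r_i²/(2σ_tot²)) / (2πσ_tot²)` assembled into a
  sparse influence matrix (compiled with Rcpp).
* **Optimisation** — non-negative fluence-map optimisation (L-BFGS-B)
  of quadratic uniform/max/mean/DVH-max objectives, then prescription
  normalisation (target mean = 100 %).
* **Evaluation & sweeps** — DVHs, Dx%, D_1cm³, V_xGy, homogeneity index
  `(D2−D98)/D50`, and an automated sweep over beam number × energy ×
  spot spacing with tidy CSV output and reference-difference tables.

See `vignettes/vhee-planning-methods.Rmd` for the model, its assumptions,
parameter defaults, and known limitations.

## Worked example

A prostate-style plan on the synthetic pelvis phantom (3 mm grid for
speed; the default is 2 mm), five equidistant beams over 360°, 200 MeV,
sigma0 = 4 mm, 1.5 sigma spot spacing:

```r
library(vheetps)

bd <- generate_analytic_base_data(beam_energy_spec(200, 4))
bd
#> <vhee_base_data> 200 MeV, sigma0 4 mm, 351 depths to 350 mm (analytic)
sprintf("sigma_tot(4 mm, z = 150 mm) = %.2f mm; FWHM(42 mm) = %.2f mm",
        sigma_total(4, 150, bd), fwhm_from_sigma(42))
#> "sigma_tot(4 mm, z = 150 mm) = 5.73 mm; FWHM(42 mm) = 98.90 mm"

pelvis <- make_phantom(phantom_spec("pelvis", spacing = 3))
pelvis
#> <vhee_structure_set> grid 104x71x54 @ 3x3x3 mm
#>   ptv          target       78.7 cm^3
#>   rectum       oar          71.3 cm^3
#>   bladder      oar         192.5 cm^3
#>   body         external   7642.8 cm^3

plan <- run_plan(pelvis, n_beams = 5, span = 360, energy_mev = 200,
                 sigma0 = 4, spacing_k = 1.5,
                 objectives = protocol_objectives("prostate"),
                 prescription_gy = 60, seed = 1)
plan
#> <vhee_plan> pelvis: 5 beams, 200 MeV, 1.5 sigma spacing, 427 spots (543 / 100 cm^3)
#>   converged: FALSE after 519 evaluations (objective 27.87)

subset(plan$metrics, structure %in% c("ptv", "rectum"))
#>  structure metric       value
#>        ptv   D50% 60.00833899
#>        ptv   D98% 58.83977134
#>        ptv   D95% 59.51720856
#>        ptv    D2% 60.84330628
#>        ptv  Dmean 60.00000000
#>        ptv  D1cm3 61.25495271
#>        ptv     HI  0.03338761
#>     rectum  Dmean 24.01561223
#>     rectum    D2% 54.13570046
#>     rectum  D1cm3 55.24935573
#>     rectum  V20Gy 54.69696970
#>     rectum   V5Gy 66.66666667
```

Reading the numbers: the plan is normalised so the PTV mean is exactly
the 60 Gy prescription; D98/D95 near 59 Gy and HI = 0.033 indicate a
homogeneous target dose; the rectum (abutting the PTV posteriorly) keeps
a mean of 24 Gy. `converged: FALSE` means the optimiser used its full
500-iteration budget rather than reaching the gradient tolerance — the
plan is still valid; the flag is diagnostic.

The sweep driver runs whole studies (here: 2 beam counts × 2 energies):

```r
cfg <- study_config(list(pelvis = pelvis), beam_counts = c(3, 5),
                    energies = c(150, 200), spacings = 1.5,
                    prescription_gy = 60)
sweep <- run_sweep(cfg)
head(sweep$records)
```

A command-line front end is installed with the package
(`system.file("cli", "vheetps", package = "vheetps")`):

```sh
vheetps basedata --out basedata/
vheetps phantom --config phantom.json --out phantom/
vheetps sweep --config study.json --out results/ --seed 1
```

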