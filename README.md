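# vesselquant

Quantitative image analysis for microvessel-on-chip extravasation assays.

Perfused, cylindrical endothelial vessels grown in collagen hydrogels are a
standard platform for studying how hemodynamics and matrix mechanics
regulate barrier function and immune-cell extravasation. The raw readouts
are microscopy stacks; the numbers biologists report are derived
quantities. `vesselquant` implements those derivations as a tested,
scriptable pipeline:

* **Diffusive permeability** `P_d` (µm/s) from dextran time-lapse imaging
  via the cylindrical mass balance `P_d = (r / 2·I₀) · (δI_out/δt)`,
  where `r` is the vessel radius, `I₀` the total lumen intensity and
  `δI_out/δt` the early-time growth rate of exterior intensity.
* **Interstitial flow velocity and Darcy hydraulic permeability**
  `k = v·µ·L/ΔP` (m²) from FRAP: a photobleached spot is tracked with
  subpixel dip fits, its velocity fit by least squares, and the applied
  head (mmH₂O) converted at 9.80665 Pa/mmH₂O.
* **Fiber alignment index** `α ∈ [0, 1]` of actin/VE-cadherin textures:
  gradient-energy orientation spectra of wall-excluded square FFT patches,
  pooled into the axis-referenced doubled-angle resultant
  `α = max(0, Σw·cos 2(θ − axis) / Σw)` (1 = parallel to the vessel,
  0 = isotropic).
* **Monolayer continuity and vessel diameter** from junction segmentation
  (connected components at 8-connectivity) and transverse wall profiles
  (outermost half-maximum crossings, median over columns).
* **3D monocyte scoring**: nucleus detection in z-stacks
  (difference-of-Gaussians + seeded region growing), monocyte vs
  endothelial classification by size and roundness, adhered vs
  extravasated classification by radial excess `ρ − r` from the vessel
  axis, and migration distances.
* **Condition statistics**: one-way ANOVA with significance stars, Tukey
  1.5·IQR outlier flags (flagged, never removed), per-condition summary
  tables.

Because no raw imagery is deposited for assays of this kind, the package
ships a first-class **synthetic-phantom generator** with known ground
truth for every stage, including named presets that pin phantom truths to
reported condition means (`"static-2.5mg"` → P_d 1.45 µm/s, `"flow-2.5mg"`
→ 0.10, `"flow-6mg"` → 0.60, `"migration-20um"`, `"counts-static"`,
`"diam-hi"`/`"diam-lo"`, `"aligned"`/`"random"`). Every estimator is
validated by parameter recovery against these phantoms. See the methods
vignette (`vignettes/vesselquant-methods.Rmd`) for models, assumptions,
and numerical choices.

## Worked example

```r
library(vesselquant)

# 1. permeability: simulate the 6 mg/ml-collagen condition and recover P_d
sim <- simulate_preset("flow-6mg", seed = 1)       # truth: 0.60 um/s
res <- measure_pd(sim$stack)
#> P_d = 0.571 um/s (truth 0.60), fit R^2 = 1.000, window frames 1-11
```

The ~5% deficit is the systematic cost of the 2-px wall guard band (the
excluded annulus hides a boundary-layer mass fraction ~ w/sqrt(pi*D*t));
it is analysed, not hidden — see the vignette.

```r
# 2. alignment: a perfectly parallel texture scores alpha ~ 1
al <- measure_alignment(simulate_preset("aligned", seed = 1)$image,
                        axis_angle_deg = 0)
#> alpha = 0.982 over 100 patches

# 3. extravasation scoring on a 3D nuclear stack
sim <- simulate_preset("migration-20um", seed = 2) # truth: mean 20 um
v <- attr(sim$truth, "vessel")
s <- score_extravasation(sim$stack, list(radius_um = v$radius_um,
                                         axis_y_um = v$axis_y_um,
                                         axis_z_um = v$axis_z_um))
#> adhered = 4, extravasated = 30, mean migration = 19.7 um

# 4. condition comparison, reported the way the figures report it
one_way_anova(list(static = c(1.31, 1.52, 1.47, 1.38, 1.62),
                   flow   = c(0.09, 0.12, 0.08, 0.11, 0.10)))
#> ANOVA: F = 624.9, p = 7e-09 ***
```

All numbers above are actual package output at the stated seeds.

## Command line

```sh
Rscript -e 'vesselquant::run_cli(commandArgs(TRUE))' \
  simulate --preset static-2.5mg --seed 1 --out out/
Rscript -e 'vesselquant::run_cli(commandArgs(TRUE))' \
  permeability out/static-2.5mg-seed1.tif --pixel-size-um 1 --step 5 --out out/
```

Subcommands: `simulate`, `geometry`, `permeability`, `frap`, `align`,
`extravasation`, `report`. Inputs are multi-page grayscale TIFF; outputs
are CSV/JSON. A launcher script is installed at
`inst/scripts/vesselquant`.

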