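---
title: "Quantifying microvessel-on-chip assays: models, estimators, and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvessel-on-chip assays: models, estimators, and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

# The measurement problem

Microfluidic vessels-on-chip recreate a perfused, cylindrical endothelial
monolayer embedded in a collagen hydrogel. A typical experiment asks five
quantitative questions of its image data:

1. **How leaky is the endothelial barrier?** Fluorescent dextran is perfused
   through the lumen and its escape into the gel is imaged over time; the
   diffusive permeability $P_d$ (µm/s) summarizes the barrier.
2. **How permeable is the gel itself to bulk flow?** A hydrostatic head
   drives interstitial flow; a photobleached spot (FRAP) acts as a passive
   tracer whose displacement gives the flow velocity, and Darcy's law
   converts velocity to a hydraulic permeability $k$ (m²).
3. **Is the monolayer intact, and how big is the vessel?** Junction
   (VE-cadherin) staining is segmented and checked for connectivity; the
   phalloidin-stained walls give the diameter.
4. **Is the cytoskeleton aligned with flow?** An alignment index
   $\alpha \in [0,1]$ summarizes how strongly actin/junction textures
   parallel the vessel axis.
5. **How many monocytes adhere, how many extravasate, and how far do they
   migrate?** DAPI-stained nuclei are counted in 3D and classified by type
   and by radial position relative to the vessel wall.

No raw imagery is publicly deposited for assays of this kind, so every
estimator in this package is validated by *parameter recovery on synthetic
phantoms*: the generator modules produce images from known ground truth,
and the analysis modules must recover that truth within stated tolerances.
The preset table (`get_preset()`) pins phantom ground truths to the
reported condition means of the motivating study (static vessels
$P_d = 1.45$ µm/s, flow-conditioned $0.10$ µm/s, 6 mg/ml collagen
$0.60$ µm/s, migration distance $\approx 20$ µm, diameters 125–250 µm,
static adhered counts $\le 10$ per vessel, flow counts 5–20).

# Diffusive permeability

## Model

For a cylinder of radius $r$ whose lumen holds total (cross-sectional)
intensity $I_0 = C_0 \pi r^2$, a wall flux $P_d (C_\text{lumen} -
C_\text{wall})$ through the perimeter $2\pi r$ gives, while the exterior
behaves as a sink ($C_\text{wall} \approx 0$),

$$\frac{dI_\text{out}}{dt} = \frac{2 P_d I_0}{r}
\quad\Longrightarrow\quad
P_d = \frac{r}{2 I_0} \frac{\delta I_\text{out}}{\delta t}.$$

This is the unique arrangement of the three named quantities ($r$, $I_0$,
$\delta I/\delta t$) with velocity units, and it is exact for the 2D mass
balance. `measure_pd()` implements it as: locate the lumen circle
(`locate_lumen_circle()`), extract guard-banded intensity traces
(`extract_traces()`), fit the early-time slope (`fit_leak_rate()`), apply
the relation (`compute_pd()`).

## The phantom's two transport regimes

`simulate_dextran_timelapse()` holds the lumen at constant intensity (it is
continuously fed from dextran-filled reservoirs) and advances the exterior
concentration on a radial finite-volume grid. The wall flux has two modes:

* **`membrane-limited`** (default): flux $= P_d C_\text{lumen}$. The
  endothelium is the rate-limiting resistance — the regime in which the
  estimator above is *valid* — and exterior growth is exactly linear, so
  recovery tests measure the estimator's measurement error, not a model
  mismatch.
* **`series`**: flux $= P_d (C_\text{lumen} - C_\text{wall})$ with
  $C_\text{wall}$ the evolving gel concentration at the wall. With the
  default gel diffusivity $D = 25$ µm²/s (typical for 70-kDa dextran in
  collagen) the wall saturates on the time scale $D/\pi P_d^2$ — under
  0.4 s at $P_d = 1.45$ µm/s, i.e. within a fraction of one 5-s frame. Any
  early-slope estimator is then biased low by 30–60%. This regime is
  exposed because it is the honest coupled physics; a characterization
  test documents its bias. Real measurements at high $P_d$ carry the same
  bias, which is one reason printed permeability values should be read as
  operational, estimator-defined quantities.

The default is `membrane-limited` because (a) it is the regime the
estimator assumes and the regime a tight monolayer actually sits in, and
(b) a recovery benchmark should present the estimator with data generated
under its own model so that failures indicate implementation defects.

## Acquisition geometry and residual bias

Defaults mirror the assay: 50 frames at 5 s, radius 100 µm, imaged at
1 µm/pixel over a 640-µm field (a 10×-objective crop) with 2% additive
noise over a camera baseline offset. Three choices matter and are worth
stating bluntly:

* **Field of view.** The diffusion front travels
  $\sqrt{2 D t} \approx 110$ µm during the movie; a field that clips the
  front loses exterior mass and the measured slope with it (a 320-µm field
  costs up to 45% of the late-time slope). The 640-µm field keeps the
  front interior for the whole movie; real 10× fields are wider still.
* **Camera baseline.** Intensities are non-negative, so noise on a
  zero-baseline exterior clips to a half-normal residue that *decays* as
  dextran accumulates, depressing the measured slope (−20% at
  $P_d = 0.1$ µm/s). Detectors are bias-offset precisely to avoid this;
  the phantom adds a 100 a.u. offset, and the estimator's first-frame
  background subtraction removes it by construction.
* **Wall guard band.** Both ROIs exclude 2 px around the wall so the
  endothelium contaminates neither trace. The price is a boundary-layer
  mass fraction $\approx w/\sqrt{\pi D t}$ hidden in the excluded annulus
  ($w$ = band width), which gives the estimator a systematic deficit of
  about 5% — the dominant residual error, identical across $P_d$ values,
  and visible in the acceptance results (recoveries cluster at
  $0.95 \times$ truth). We leave it uncorrected: correcting it would
  require knowing $D$, and the estimator is deliberately $D$-free.

The auto fit window is the longest initial span with
$I_\text{out} \le 20\%$ of its final value (minimum 5 frames, else the
first half of the series); this guards against the trace flattening as the
gel approaches equilibration, which real static vessels show within
~100 s.

# FRAP velocimetry and Darcy's law

The bleached spot is modeled as a radially symmetric Gaussian dip
(depth × background, $\sigma_0$ = half the 50-px-diameter spot radius —
the protocol's "50 pixel circle" is read as a diameter) that advects
with the flow and relaxes diffusively ($\sigma^2(t) = \sigma_0^2 + 2Dt$
with mass-conserving amplitude). `detect_spot()` fits
$\text{offset} - A \exp(-\rho^2/2\sigma^2)$ by least squares for a
subpixel center (a deficit-centroid provides the initial guess and an
independent test oracle); `track_spot()` chains detections with the
previous center as prior and stops after 3 consecutive failures rather
than interpolating through them; `fit_velocity()` fits separate lines to
row(t) and col(t). Velocity is invariant to intensity gain and offset
because only the fitted amplitude and offset absorb them.

`darcy_permeability()` computes $k = v \mu L / \Delta P$ with
$\Delta P = 9.80665\,\text{Pa}$ per mmH₂O. Defaults are explicit about
what the protocol leaves unstated: viscosity $\mu = 0.7$ mPa·s (aqueous
buffer at 37 °C) is configurable and always reported; the channel gap $L$
has **no default** — device geometry must be supplied, preventing silent
unit errors; the spot velocity is equated to the superficial Darcy flux
(porosity 1, configurable). No printed $k$ value exists to compare
against, so the acceptance property is the linearity the three-head
design implies: phantoms generated with $v \propto \Delta P$ at 5/10/20
mmH₂O must return a constant $k$ (CV ≤ 10%).

# Fiber alignment index

Orientation is axial data ($\theta \equiv \theta + 180°$), so dispersion
is modeled on the doubled angle: fiber angles are drawn with
$2(\theta - \text{axis}) \sim \text{von Mises}(0, \kappa)$, giving the
closed-form population alignment
$E[\cos 2(\theta - \text{axis})] = I_1(\kappa)/I_0(\kappa)$ — the
test oracle. The estimator tiles the image into 64-px patches (patches
touching the wall bands are excluded so the bright walls cannot vote for
the axis direction), Hann-windows and Fourier-transforms each patch, bins
spectral energy by orientation (fiber angle = spectral angle + 90°), and
pools the energy-weighted doubled-angle resultant
$\alpha = \max\!\big(0, \sum w \cos 2(\theta - \text{axis}) / \sum w\big)$,
reporting the signed value alongside for perpendicular-dominated textures.

Two numerical choices keep the index honest:

* **Gradient-energy weighting.** The spectrum is weighted by $|k|^2$
  (equivalently: orientation energy of the image gradient, the
  Fourier-domain structure tensor). Plain power weighting cannot reach
  $\alpha = 1$ even for ideal parallel stripes: DFT leakage spreads each
  coefficient's angle by $\sim 1/|k|$, and low frequencies dominate raw
  power, leaving a 4–13% deficit. With $|k|^2$ weighting the parallel
  phantom measures $\alpha \approx 0.98$. A `weighting = "power"` mode is
  retained for comparison.
* **Band limits.** Frequencies below 2 cycles/patch (residual illumination
  gradients) and above 0.7 × Nyquist are excluded; the near-Nyquist band
  is dominated by pixel aliasing and is what breaks rotation invariance if
  retained (rotating image and axis together then shifts $\alpha$ by
  0.03; with the 0.7 cutoff the shift is under 0.02).

The fiber phantom renders long strands (200 px, spanning several patches)
because actin stress fibers and junction lattices span whole cells; short
segments would add isotropic "end-cap" spectral energy that depresses
$\alpha$ for reasons that have nothing to do with orientation dispersion.

# Vessel geometry

Junction masks come from simple thresholding (Otsu by default, fixed
threshold for reproducibility) followed by removal of objects smaller
than 10 px, so that isolated noise cannot defeat the continuity check.
Monolayer continuity is the connected-component structure of the mask at
8-connectivity (diagonal strands are common in junction lattices;
4-connectivity is available): a continuous monolayer is a single object,
and each severed lattice column adds one object.

Diameter is measured per column from the transverse intensity profile:
wall positions are the outermost half-maximum crossings (subpixel by
linear interpolation), separation is corrected by the axis tilt estimated
from a line fit through per-column intensity centroids, and the summary
is the median over columns. Columns whose above-half-maximum support is a
single contiguous band are rejected — that is what one wall out of field
looks like. The cylinder-projection phantom defines `diameter_um` as the
**outer wall envelope** and renders wall-band edges as ramps centered on
the boundary (the pixel-coverage convention), so the half-maximum
crossing sits exactly on the stated diameter; phalloidin stains the cell
body, making the outer envelope the natural "vessel diameter". Recovery
at the printed range endpoints (125 and 250 µm) is exact to well under
the 2 µm tolerance, and a 10° tilt changes the estimate by < 0.5%.

# Extravasation scoring

The study counted nuclei manually; this module automates the same
criteria so results are reproducible. Detection: difference-of-Gaussians
band-pass (2 and 6 µm scales, bracketing 5–15 µm nuclei), 3D local maxima
at least 6 robust noise SDs above zero as seeds, then region growing over
voxels above half the typical nucleus amplitude, restricted to
26-connected components containing a seed (scattered supra-threshold
noise voxels must not be swept in) and split between nearby seeds by
nearest-seed assignment in physical micrometres (anisotropy-aware).
Shape moments are intensity-weighted with a Sheppard voxel-size
correction and trimmed to 1.25 equivalent radii around the bright core,
so a touching neighbour's annexed voxels cannot distort the axis ratio.

Classification mirrors the field's criteria: a monocyte is *small*
(equivalent diameter ≤ 9 µm; phantom classes are 7 vs 12 µm) *and round*
(sphericity = minor/major SD ratio ≥ 0.8; monocyte nuclei are rendered
as spheres, endothelial nuclei as wall-hugging flattened ellipsoids).
Position is radial: with $\rho$ the centroid's perpendicular distance to
the vessel axis, the radial excess $\rho - r$ classifies cells as
luminal-free ($< -5$ µm), luminal-adherent ($|\cdot| \le 5$ µm — about
one endothelial cell thickness, the protocol states no numeric
criterion), or extravasated ($> 5$ µm); migration distance is the radial
excess of extravasated monocytes. Counts on noise-free phantoms are
exact; at 2% noise they are within 1 per class in ≥ 90% of stacks.

Known limitation: at z-steps ≥ 3 µm a 7-µm nucleus spans barely two
slices and its *sphericity* loses fidelity (positions, and therefore
counts-by-position and migration distances, do not). The default phantom
z-step is 2 µm; if acquisition uses coarser stacks, relax
`min_sphericity` or classify on diameter alone.

# Statistics

Condition comparisons follow the reporting conventions of the figure
captions: one-way fixed-effects ANOVA (`one_way_anova()`, with the
two-group case equal to the squared pooled-variance t statistic — tested
numerically), stars at p < 0.05/0.01/0.001, Tukey 1.5 × IQR fences for
outliers which are *flagged but never excluded* (the plots show them as
crosses; nothing suggests exclusion), and per-condition mean/median/range
tables (`summarize_conditions()`). No multiple-testing correction by
default, matching unadjusted per-figure reporting; a Bonferroni option
exists.

# What the phantoms do and do not establish

The generators emulate: reservoir-fed lumen leakage with radial gel
diffusion; advected, diffusively recovering bleach spots; von Mises
oriented fiber textures; cylinder-surface endothelial nuclei with
adhered/extravasated monocyte populations at truncated-normal migration
distances (mean 20 µm, SD 5 µm — the study reports only "around 20 µm");
junction lattices and wall projections. They deliberately omit: optical
PSF and depth attenuation, photobleaching during acquisition, cell
morphology beyond nuclei, monocyte rolling dynamics, and non-circular
lumen cross-sections. A green recovery test therefore establishes that
the estimators are correct *for data matching their stated acquisition
model*, with noise; it does not certify performance on degraded optics
or deformed vessels. Seeds flow from one global seed through a
counter-based expansion (`stage_seed()`), so each stage is independently
reproducible and identical configuration yields bitwise-identical
phantoms.
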