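---
title: "Methods: orientation-field estimation and nerve fiber bundle tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation-field estimation and nerve fiber bundle tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rnfbtrace)
```

## The problem

Retinal nerve fiber bundles (RNFBs) are the axon bundles of retinal
ganglion cells; they run from their retinal origin to the optic nerve head
(ONH), and their trajectories link locations on the retina (and the visual
field positions they serve) to positions on the ONH circumference.
Glaucoma damages these bundles sector by sector, so knowing the individual
trajectory geometry of an eye — rather than a population average — matters
for structure–function mapping.  Manual tracing on fundus images is slow
and only moderately reproducible.  This package implements a fully
automatic alternative: estimate a dense en-face *orientation field* of the
nerve fiber layer from several complementary sources, fuse them, and
integrate trajectories through the fused field.

Everything operates on *axial* angles — a fiber defines a line, not an
arrow, so orientation lives on the half-circle `[0, 180)` degrees.  All
averaging, interpolation and distance computation is done on the doubled
angle, where the representation `(sin 2φ, cos 2φ)` removes the wraparound.
This is the single most important numerical convention in the package:
interpolating raw angles across the 0/180 cut produces garbage, doubled
components never do.

## The three orientation sources

### 1. Parametric average-trajectory model (`model_constants`, `trajectory`, `rasterize_model`)

A population-average model describes each bundle in a polar frame around
the ONH as `ψ(ψ0, r) = ψ0 + b(ψ0) (r − r0)^c(ψ0)`, with `r0 = 4°` the ONH
entry circle and hemifield-specific tanh laws for `b` and `c` (superior
`b > 0`, inferior `b < 0`).  The model frame places the fovea at the
origin and the ONH 15° along +x.  The angular reference is not stated
uniformly in the literature; we measure `ψ` from the nasal horizontal
(superior positive, raphe at ±180°), the only reading under which the
fitted constants are anatomically coherent: the papillomacular bundle
(`|ψ0| → 180`) is nearly straight (`b → e^{−5.8}`), arcuate bundles curve
toward the temporal raphe, and nasal bundles fan.  Reported entry angles
are converted to the conventional reference (0 at the temporal
horizontal, superior positive).

Per eye, the model is fitted with a similarity transform: translation
matches the fovea, then rotation and scaling about the fixed fovea match
the ONH center; left eyes are mirrored to right-eye convention and back.
The transform is computed in micrometers so anisotropic pixels are exact.
Rasterization generates one trajectory per degree of starting angle,
samples positions and *analytic* tangents every 0.1° of eccentricity, and
interpolates the tangent field to the pixel grid by binning the
doubled-angle components and gathering with an inverse-distance-squared
kernel of 1° radius.  Pixels farther than 1° from any trajectory sample
(the wedge on the nasal horizontal just past the ONH, the raphe, the ONH
interior) stay invalid; where a dense field is needed they are filled by
doubled-angle diffusion from the surrounding field.

A caveat worth knowing: at the raphe the superior and inferior halves of
the model meet at steep opposing angles, so the model field is genuinely
discontinuous there.  Tests and error budgets therefore exclude a 2° band
around the raphe (and the fovea, where bundles converge from all
directions).

### 2. Polarization (PS-OCT) axis maps (`average_stokes`, `extract_polarization_maps`)

The nerve fiber layer is birefringent; polarization-sensitive OCT measures
per-voxel retardation `δ` and optic-axis orientation `θ`.  Because the
layers between the ganglion cells and the outer plexiform layer preserve
the polarization state set by the RNFL above them, averaging the
normalized Stokes vector `(cos 2δ, sin 2δ cos(π − 2θ), sin 2δ sin(π − 2θ))`
over exactly the `BOO − BNG` depth samples below the RNFL/GCL boundary and
re-normalizing gives a robust 2-D retardation map `δP = arccos(Q_R)/2` and
axis map `φP = atan2(−V_R, U_R)/2`.  The two-argument arctangent is used
so the quadrant of `(−V, U)` survives the halving.  Two numerical notes:

* The parameterization carries a fixed quarter-turn — a depth-constant
  axis `θ0` comes back as `θ0 − 90°`.  We leave it: the PS-OCT axis is a
  *relative* angle in any case and is offset-calibrated against the
  intensity field downstream, which absorbs any constant.
* Pixels whose averaged vector norm falls below 0.1 are marked invalid:
  a shrunken norm means the polarization state was not constant in depth,
  so the axis there is unreliable.  The threshold is exposed
  (`norm_threshold`).

### 3. Intensity ridge orientation (`project_rnfl` … `smooth_orientation`)

Bundles reflect more strongly than their surround, so an en-face mean over
the band of at most `MaxLen = 15` voxels immediately above the RNFL/GCL
boundary (never crossing the ILM) shows them as bright ridges — an image
with fingerprint-like statistics.  The orientation pipeline is the
classical fingerprint one, made mask-aware throughout (vessel pixels
contribute to no window sum):

1. background subtraction in a 145 × 145 px window (≈1.2 mm at the native
   8.2 µm pitch; on coarser grids the same *physical* window is used) and
   robust rescale to `[0, 1]` by the 1st/99th percentiles;
2. 3 × 3 Sobel gradients, divided by the pixel pitch per axis so the
   tensor lives in physical space and anisotropic pixels do not bias
   angles; windowed tensor sums with half-size `N = 7`;
3. initial orientation `φFI` perpendicular to the dominant gradient,
   `φ = ½·atan2(2Gxy, Gxx − Gyy) + 90°`;
4. reliability weights from two distances: to the model field (`DSTm`) and
   to the windowed neighborhood mean (`DSTn`), both as doubled-component
   distances in `[0, 2]`, window-averaged, combined as
   `W = 1 − ½√(D̄m² + D̄n²)` and clamped to `[0, 1]`;
5. a large weighted doubled-angle average (half-size `N_max = 30` px) whose
   window shrinks near the fovea so that it never contains the fovea pixel
   (bundles converge there from all directions; averaging across the
   fovea would destroy the structure).  Only `N = 7` and the 145-px window
   are literature-fixed; the remaining window sizes (`DSTn` half-window 7,
   weight smoothing 15, `N_max` 30) are package defaults, all exposed.

### Fusion (`find_axis_offset`, `source_weight`, `fuse_maps`)

The polarization axis is offset by an unknown constant.  In an annulus of
5–10° eccentricity around the ONH (high retardation, both maps reliable)
the sum of squared doubled-component differences between `φP + ofs` and
`φF` is evaluated for `ofs ∈ {−90, …, +90}` in 1° steps; the argmin is
applied to `φP`.  Both corrected maps are then weighted by agreement with
the model (`W = 1 − ½·axial distance to φM`), the weights are smoothed
with a 15-px sliding mean, and the maps are merged as a weighted
doubled-angle mean.  Where neither source is valid (or they cancel
exactly), the model field fills the gap, blended over a 10-px linear ramp
to avoid orientation seams.

### Tracing (`trace_inward`, `trace_through_point`)

Trajectories are streamlines of the fused field with a fixed physical
step (default 1 px ≈ 8.2 µm at native pitch; positions are kept in
micrometers so steps are isotropic regardless of pixel shape).  An axial
angle gives two antipodal step candidates; inward tracing keeps the one
closer to the ONH center.  Tracing inward — periphery toward the ONH — is
the robust direction: bundle paths converge on the ONH, so orientation
errors contract along the trace instead of diverging.  After the first
step an anti-reversal rule takes precedence: the candidate most aligned
with the previous heading wins, which prevents 180° oscillation where the
field runs perpendicular to the radial direction (near the raphe).  The
practical entry point is `trace_through_point()`: both sub-traces from a
point of interest, concatenated periphery-to-ONH.

### Evaluation (`to_polar`, `entry_angle_stats`, `icc_ak`, `trace_rmse`, `build_report`)

Traces are resampled in polar coordinates around the ONH (0.1° radial
grid, angles unwrapped along the trace).  The entry angle (EA) is the
angle at which a trace crosses the 4° ONH circle.  Agreement between
raters (or between repeated automatic runs, which is statistically the
same question) is summarized by the circular EA range (max pairwise
wrapped difference), the mean circular deviation from the circular mean
EA, the polar-resampled trace RMSE (wraparound-minimal angular differences
converted to arc micrometers, root-mean-squared per trace, averaged over
traces), and ICC(A,k) — two-way random effects, absolute agreement,
average of k raters — computed from classical mean squares after
unwrapping each trace's EAs to within 180° of their circular mean.
Degenerate circular means (opposed angles) raise errors rather than
returning numbers.  Sector rows follow the six Garway-Heath ONH sectors;
SDs are over traces.  The shipped 24-2-point-to-sector table is
model-derived (entry angles binned into the published sector boundaries)
and editable — it is a synthetic stand-in for the original hand-drawn map,
and is labeled as such.

## The phantom generator

`phantom_spec()` + `simulate_phantom()` produce every input from a known
ground truth so each stage is testable without instrument data:

* **truth field** — the rasterized model field, diffusion-filled dense;
* **projection** — streamlines of the truth field placed one ridge period
  apart (Jobard–Léfer-style occupancy seeding), stroked with Gaussian
  cross-profiles: the rendered texture's local orientation equals the
  truth by construction.  Dark vessel arcades are stamped and recorded in
  the vessel mask; Gaussian noise is added last.
* **PS-OCT stack** — depth-constant axis rotated by the phantom's
  `axis_offset_true` (in the instrument convention, so the calibration
  search recovers `+axis_offset_true`), constant retardation 0.35 rad,
  smooth synthetic boundaries with RNFL thickness 5–40 voxels, and the
  projection embedded as the bright band above the RNFL/GCL boundary;
* **degrade()** — SNR-calibrated Gaussian noise plus random block dropout,
  deterministic per seed.

Default conditions: a 50° × 44° field on an isotropic 32.8 µm grid (the
native fast-axis pitch downsampled 4×, used for both axes: at the ~100 µm
native slow-axis pitch, realistic 200–300 µm bundle striations would sit
at or under the two-sample limit vertically and the rendered ridges would
alias), ridge period 300 µm, contrast 0.5, six vessels, axis offset 30°.
These sizes also keep the full test suite in the minutes range; the same
code runs unchanged on larger grids.

What the phantom does *not* emulate: OCT speckle statistics, real vessel
shadow artifacts, segmentation errors in the layer boundaries, pathology
beyond SNR/dropout degradation, and the stitching seams of mosaicked
wide-field acquisitions.  Passing phantom tests therefore demonstrates
correctness of the estimators and tracer under controlled conditions, not
clinical performance.

## Numerical choices and degenerate inputs

* Interpolation (rotation, map sampling, tracing) is always bilinear on
  doubled-angle components with the validity mask as weight.
* A zero doubled-angle resultant (perpendicular inputs with equal weight)
  is treated as *undefined*: scalar means raise an error, per-pixel means
  mark the pixel invalid and let the model fill it.
* The offset search breaks ties toward the smallest |offset|.
* Constant images are flagged `degenerate` by the normalizer and return
  mid-scale, rather than amplifying numerical noise.
* Traces record their termination (`onh_reached`, `boundary`,
  `invalid_pixel`, `max_steps`); entry angles are only defined for traces
  that reach the 4° circle.
* Anisotropy is handled once, at the physical-coordinate boundary:
  gradients are per-micrometer, steps are micrometer-isotropic, rotations
  act in micrometer space.

## Known limitations

* Near the raphe the direction choice is genuinely ambiguous; the heading
  rule prevents oscillation but cannot decide the correct hemifield for a
  seed sitting on the seam (the clinical literature reports the same
  failure for human graders).
* The ridge estimator carries a sub-degree orientation bias where ridges
  are strongly curved and convergent (near the ONH); it is visible as a
  ±1-step uncertainty in the 1°-resolution axis-offset search.
* The trajectory model is a population average of healthy eyes; its use
  as prior and gap filler biases orientation estimates toward it in
  low-information regions.
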