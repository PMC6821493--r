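---
title: "Quantifying cSMAC formation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cSMAC formation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmacq)
```

This vignette is the package's own account of what it computes and why the
open design choices were resolved the way they were. The pipeline
quantifies micrometre-scale protein accumulation at the T cell:APC
interface from 3D time-lapse fluorescence volumes, sizes supramolecular
puncta in deconvolved super-resolution stacks, and measures membrane
undulations on traced EM sections, with a statistics layer for the
resulting time-course proportions.

## The measurement model

A cell couple movie is a series of 3D stacks (voxels 0.34 µm laterally,
1 µm axially; one stack every 20 s). Analysis of a couple starts at
*tight coupling* — the frame where the interface first reaches its full
width, or 40 s (two frames) after first contact, whichever is earlier.
"Full width" is inherently a visual notion; `detect_tight_coupling()`
operationalizes it as 90% of the steady-state width, with steady state
the median width over the final quarter of the movie. Both constants are
arguments.

Within each frame the T cell is segmented by Otsu thresholding restricted
to a neighbourhood of a seed point (twice the expected cell radius) and
connected-component selection. The *cellular background* is the median
intensity over the cell mask — robust because even a large accumulation
occupies a minority of the cell volume. An *accumulation region* is the
largest 26-connected component of voxels strictly above 1.4× background
(the "more than 40% above background" criterion; a region at exactly
1.4× does not qualify), discarded if smaller than 0.2 µm³.

### Detection-scale smoothing

Detection applies an in-plane 3×3 box mean before thresholding (the axial
spacing is already comparable to the feature scale). The rationale is
scale, not aesthetics: an accumulation region is a micrometre-scale
structure several lateral voxels across, whereas uncorrelated shot noise
lives at single-voxel scale. Without smoothing, a pattern-free noisy cell
frequently produces two-voxel supra-threshold clusters that clear the
0.2 µm³ floor. On noise-free data the smoothing changes nothing in region
interiors, so the strict boundary semantics above are preserved; the
boundary unit test runs with `smooth = FALSE` to pin them down exactly.

## The six-pattern classifier

The quantitative criteria behind the published six-pattern vocabulary live
in prior work that this package does not reproduce; the classifier
therefore fixes its own explicit, config-exposed criteria
(`pattern_thresholds()`), designed so that each scripted synthetic
geometry round-trips to its label. Features measured on the detected
region (against the interface disc estimated from the top of the cell
mask):

* `coverage` — area of the region's projection onto the interface disc,
  over the disc area;
* `radial_fraction` — mean in-plane radial distance of region voxels,
  over the disc radius;
* `depth` — maximum extension below the interface plane (µm), with
  `deep_volume`/`deep_radial` summarizing the voxels at or beyond the
  1.5 µm interface shell and `ext_volume` those at or beyond 1 µm;
* rim structure — the number of supra-threshold components contacting the
  rim band (radial fraction ≥ 0.75) and whether their azimuthal span
  exceeds 180° (`annular`).

Decision order: **invagination** (deep voxel set clears the 0.2 µm³ noise
floor and sits centrally, radial ≤ 0.5) → **diffuse**/**lamellal**
(coverage > 0.6, split by whether the ≥1 µm cortical extension clears the
same floor) → **central** (radial ≤ 0.5) → **peripheral** (annular or ≥ 2
rim components) → **asymmetric**. Exactly one label results for any
feature record; no region means `none`.

Two features deliberately deviate from the more obvious definitions.
First, the radial position uses the *mean per-voxel* radial distance, not
the distance of the centroid: an annular peripheral region has its
centroid on the synapse axis, which would score it as maximally central.
Second, the depth tests compare the *volume* of the deep voxel set against
the detection noise floor rather than using the raw maximum depth: under
Poisson noise a single stray voxel attached to a shallow patch would
otherwise convert `central` into `invagination`.

## Shape standardization and enrichment

For voxel-by-voxel comparison across couples, each segmented cell is
reoriented interface-up using the two-point synapse annotation (point 1 =
interface centre, point 2 = rear pole; the rear-to-centre axis maps onto
+z by a rigid rotation about the points' midpoint, trilinear resampling,
and explicit re-normalization of the masked intensity — a rigid motion
conserves photons, and the renormalization removes the ~1–3% interpolation
loss across the coarse axial axis).

The target shape is a half spheroid holding **exactly 6628 interior
voxels** on the native anisotropic grid. The published constraint is the
count, not the semi-axes, so `build_template()` calibrates them: the
lateral semi-axis is scanned over 2–8 µm in 0.01 µm steps; for each value
the axial semi-axis achieving the exact count (a monotone step function)
is bisected for; among the exact solutions the pair with lateral/axial
aspect ratio closest to 1.5 — a moderately flattened cell — is kept. At
the default spacing this yields semi-axes of 7.00 µm (lateral) × 7.50 µm
(axial). Voxels are ordered by depth layer (interface first), then y,
then x; this fixed order resolves all ties.

Mapping is radial: for every template voxel, the ray from the template
centroid through it is matched to the same-direction ray from the cell
centroid; the cell's radial extent along that ray (found by 0.1 µm ray
marching in the mask) is linearly rescaled to the template's (closed-form
intersection with the spheroid surface or flat face). Intensity is sampled
by trilinear interpolation and divided by the interpolated mask weight, so
a uniform cell maps to an exactly uniform vector; the result is normalized
to sum 1.

The *interface enrichment region* is a dataset-level artifact: the 663
(10% of 6628) voxels with the highest average probability across all
cells, time points and sensors supplied, ties broken by template order.
Per-cell enrichment is the mean probability inside the region over the
mean over all voxels; it is bounded by 6628/663 ≈ 10.

## Puncta sizing

Deconvolved STED-like stacks are binarized at the Otsu threshold (256-bin
histogram over the whole volume) times a multiplier (default 3.5, the
published operating point). Touching particles split by seeded growth:
seeds are local maxima of the exact 3D Euclidean distance transform,
deduplicated by the rule that two candidates belong to the same particle
when their inscribed spheres overlap substantially (distance
< 0.8 × (dt₁ + dt₂); touching equal spheres sit exactly at dt₁ + dt₂ and
must stay separate) or when closer than the 0.1 µm minimum separation.
Volumes are voxel count × voxel volume.

The detection floor is empirical: the cutoff is the 95th percentile
(linear interpolation between order statistics, `quantile(type = 7)`) of
punctum sizes measured in control cells that do not express the stained
protein; retained puncta are exactly those at or above the cutoff. Group
summaries report mean volume ± SEM and mean puncta per cell, compared by
Student's t test; the cSMAC / non-cSMAC grouping is an input label, not
computed here.

The installed image-analysis package for R operates slice-wise on 3D
stacks, so the 3D primitives (26-connectivity components, exact separable
EDT, seeded growth) are implemented in this package as vectorized
whole-array passes; the slice-wise Otsu is used as an independent
cross-check in the test suite.

## Membrane undulations

On a traced 2D membrane polyline, undulation is arc length over the
straight-line diameter of the same region. The interface chord between the
annotated endpoints is cut at 1/4, 1/2 and 3/4 of its length; points are
assigned to sections by orthogonal projection, with cut points
interpolated linearly where a segment straddles a boundary, and
projections beyond the chord clamped and flagged. The central two sections
form the cSMAC (a conservative convention — real cSMACs are usually
smaller than half the diameter); the outer quarters are reported
separately as left and right pSMAC, each against its own quarter-chord,
matching the practice of measuring the periphery twice per cell. Control
couples without a cSMAC are analyzed in whole-interface mode. A section's
"diameter" is its chord portion, not its own endpoint distance, keeping
ratios comparable across regions. Ratios are computed on the raw polyline
(no smoothing) and are exactly invariant under uniform scaling.

## Statistics

Pattern proportions are compared pairwise with the pooled two-proportion
z-test, two-sided, uncorrected (α = 0.05 per comparison). Degenerate
pooled proportions (0 or 1) carry no information and return z = 0, p = 1.
Power uses the standard normal-approximation formula with the null
standard error at the pooled proportion; the worst-case convention for a
fixed 30-point difference is baseline 0.35 vs 0.65 at n = 50 per group,
all exposed as parameters, with a simulation method as a cross-check.
Chauvenet's criterion is applied in a single pass under the normal model.
Group comparisons of positive quantities (e.g. relative mRNA amounts) are
natural-log transformed before one-way ANOVA with Tukey's post-hoc or
two-way ANOVA with Sidak-adjusted pairwise comparisons. Sensor profiles
(rows of the pattern × time proportion matrix) cluster hierarchically
with 1 − Pearson distance and average linkage — the common defaults of the
classic gene-expression clustering tools, since no specific metric is
mandated — with constant rows flagged and placed at maximal distance, and
Newick export via `ape`.

## What the synthetic generator emulates — and what it does not

`make_cell_couple()` renders the T cell as a sphere (default radius 5 µm)
truncated by a planar contact disc (default radius 3 µm) — real couple
dimensions are not published, and these are plausible primary T-cell
values; the APC is present only as dark space since analysis uses the
T-cell channel. Each of the six patterns has a parametric geometry at a
scripted contrast (default 2× background): a central patch (0.45 of the
interface radius), a 0.6 µm-radius invagination reaching 2 µm below the
interface, a cortex-following diffuse shell, a sub-micrometre lamella, a
rim annulus, and a 75° rim arc. Noise is Poisson shot noise (default 50
expected photons at background) plus 2% Gaussian read noise — a generic
camera model, chosen because no noise model is published. One top-level
seed drives everything; identical configuration and seed give
bit-identical output, and cohort cells derive their seeds from the base
seed.

`make_sted_field()` renders puncta with error-function edges whose
half-maximum surface encloses exactly the requested volume, over a dark
camera floor plus a dim Gaussian cytoplasmic haze (defaults: puncta 12×,
haze 6× the floor). The haze is not decoration: on a clean two-level
image the Otsu threshold falls near the middle of the background–puncta
gap, so 3.5 × Otsu exceeds the image maximum and detects nothing. The
published multiplier presupposes histograms dominated by dim cytoplasmic
signal over a dark floor — the regime of real deconvolved stacks — where
Otsu locks onto the floor/haze split. The defaults were chosen once so
that the generator reproduces that regime; they are parameters, not
measurements.

`make_membrane_trace()` produces sinusoidal undulations, either across the
whole chord or confined to the central half (wavelength snapped to an
integer period count so the trace ends on the chord), with the true arc
length from adaptive quadrature of √(1 + A²k²cos²(kx)).

What passing tests therefore show: the pipeline recovers known geometry,
scheduled frequencies, known punctum volumes and known arc lengths from
data with the stated statistical structure. What they do not show:
performance on real microscopy — no optics beyond the PSF-like edge
profiles, no depth-dependent attenuation, no cell-to-cell shape variation
beyond the sphere model, no segmentation errors from touching same-channel
cells, no tracing error in EM sections.

## Numerical choices and problem sizes

Tolerances: probability vectors sum to 1 within 1e-9; template count is
exact; degenerate inputs (coincident annotation points, constant volumes
for Otsu, empty masks or control sets) raise errors rather than guessing.
Frame indices are 1-based throughout, as is conventional in R.

The validation suite runs at the study's own scales where those are
stated: pattern round-trips at 20 noise-free couples per label;
frequency recovery on a 60-cell cohort scheduled from 49% central at
coupling decaying to 25% by 120 s (checked against exact binomial 95%
confidence intervals of the realized counts — with 24 simultaneous time
points, a Wald band around the schedule would fail occasionally on
multinomial sampling alone even for a perfect classifier); puncta
recovery with 12 cells per group at true means 0.23 and 0.12 µm³ through
a control-calibrated filter; z-test size at 10⁴ null replicates; power at
n = 50 per group. Smaller deterministic oracles (template count,
enrichment closed forms, quadrature references) are exact.

## Known limitations

* The pattern criteria are this package's explicit operationalization of
  a vocabulary whose original numeric thresholds are not reproduced here;
  on real data they would need recalibration against expert annotation.
* The interface disc is estimated from the top layer of the segmented
  mask and slightly overestimates the contact radius for a truncated
  sphere; all radial thresholds were set with this convention.
* Whether the original standardized template used the native anisotropic
  grid or resampled isotropic units is not stated; this package fixes the
  native-grid convention, and the calibrated semi-axes are meaningful only
  under it.
* The watershed substitute (EDT-seeded growth) resolves equidistant
  boundary voxels by a fixed neighbour order rather than by intensity
  priority; for the sharp-edged puncta it targets, the difference is
  below the voxelization error.
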