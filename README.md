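# csmacq

Quantification of cSMAC formation in T cell:APC couples from 3D
time-lapse fluorescence microscopy, super-resolution puncta data and
EM-section membrane traces.

## The problem

When a T cell recognizes antigen on an antigen-presenting cell (APC), many
signaling proteins — LAT, SLP-76, Grb2 and others — accumulate transiently
at micrometre scale within the cell couple interface. Accumulation at the
interface **center** (the central supramolecular activation cluster, cSMAC)
is the form most tightly associated with efficient T-cell activation and
IL-2 production. Quantifying when and how often each sensor shows which
spatial pattern, across hundreds of cell couples and many imaging
conditions, requires a reproducible computational pipeline rather than
visual scoring. `csmacq` provides that pipeline for R, together with a
ground-truthed synthetic-data generator, so every stage can be validated
end to end without access to raw imaging data.

## What the package computes

* **Six-pattern interface classification** — per cell couple and frame,
  detect the accumulation region (voxels strictly >40% above the cellular
  background, i.e. >1.4×median over the cell mask) and assign exactly one
  of six mutually exclusive patterns from its geometry: *central*,
  *invagination* (a µm-deep intrusion below the interface center),
  *diffuse*, *lamellal*, *peripheral*, *asymmetric* — or *none*. Pattern
  frequencies are tabulated over the −40…420 s time course relative to
  tight cell coupling (time zero = full interface width or 40 s of
  contact, whichever is first).
* **Half-spheroid shape standardization** — each segmented, interface-up
  cell is mapped by radial rescaling onto a fixed half-spheroid template of
  exactly **6628** voxels on the native anisotropic grid (0.34 µm lateral,
  1 µm axial), giving a probability vector `p` (fractions of total
  intensity). Interface **enrichment** is
  `mean(p[region]) / mean(p)`, where the region is the top decile (663
  voxels) of the average distribution over all cells, times and sensors.
* **Calibrated 3D puncta sizing** — Otsu threshold × 3.5, distance-
  transform–seeded 3D splitting (seeds merged below 0.1 µm separation),
  volumes in µm³, and a detection floor set at the 95th percentile of the
  puncta sizes measured in non-expressing control cells.
* **Membrane-undulation ratios** — for a traced EM-section membrane, the
  ratio of membrane arc length to the straight-line diameter of the same
  interface region; the interface diameter is divided into four equal
  sections with the central two defined as the cSMAC.
* **Statistics** — pairwise pooled two-proportion z-tests
  (`z = (p̂₁−p̂₂)/√(p̄(1−p̄)(1/n₁+1/n₂))`) with power analysis, Chauvenet
  outlier rejection (reject i iff `n·P(|Z| ≥ zᵢ) < 0.5`), log-transform
  ANOVA with Tukey/Sidak post-hocs, and hierarchical clustering of
  sensor × (pattern, time) frequency matrices (1 − Pearson, average
  linkage, Newick export).

## Worked example

Simulate a cell couple whose LAT-like sensor is central for the first
minute, then lamellal, then gone — and classify every frame:

```r
library(csmacq)

cfg <- sim_config(n_frames = 6, seed = 7)
cc  <- make_cell_couple(cfg, pattern_script(
         c("central", "central", "central", "lamellal", "none", "none")))
ann <- synapse_annotation(1, cc$truth$interface_center, cc$truth$cell_rear)
classify_couple(cc$series, ann, cell_id = "couple01")
#>    cell_id time_s    label coverage radial_fraction depth
#> 1 couple01      0  central     0.13            0.24   0.5
#> 2 couple01     20  central     0.14            0.25   0.5
#> 3 couple01     40  central     0.13            0.24   0.5
#> 4 couple01     60 lamellal     0.88            0.63   0.5
#> 5 couple01     80     none       NA              NA    NA
#> 6 couple01    100     none       NA              NA    NA
```

The classifier recovers the scripted sequence; the feature columns show
why: the central patch covers ~13% of the interface disc near the axis,
while the lamella covers ~90% of it at sub-micrometre depth.

Standardize the first frame and score its interface enrichment:

```r
tpl <- build_template()
tpl
#> half_spheroid_template: 6628 voxels, semi-axes 7.00 (lateral) x 7.50 (axial) um
#>   spacing 0.34 x 0.34 x 1.00 um, flat face = interface plane

vol <- get_frame(cc$series, 1)
seg <- segment_t_cell(vol, cc$series$axes, seed_point = c(0, 0, 0))
sc  <- standardize_shape(vol, seg$mask, cc$series$axes, tpl)
region <- compute_enrichment_region(sc)
enrichment(sc, region)
#> [1] 1.17
```

A value of 1 would mean no interface preference; the central patch lifts
the top-decile region above the cell average. Compare pattern occurrence
between two conditions and check the design's detection power:

```r
proportion_z_test(29, 60, 15, 60)
#> two-proportion z-test: 29/60 (0.483) vs 15/60 (0.250)
#>   z = 2.652, two-sided p = 0.008

power_two_proportions(0.35, 0.65, n_per_group = 50)
#> [1] 0.862
```

So 50 couples per condition detect a 30-percentage-point difference in
pattern occurrence with power 0.86 at α = 0.05.

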