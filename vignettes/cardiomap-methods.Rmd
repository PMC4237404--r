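---
title: "Methods: voltage-map vs MRI transmurality agreement on an LV phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voltage-map vs MRI transmurality agreement on an LV phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiomap` compares two ways of measuring the same quantity — the extent
and transmurality of a left-ventricular infarct — one electroanatomical
(sparse endocardial voltage mapping) and one imaging-based (late-enhancement
MRI). This vignette is the package's own account of the models, estimators
and design decisions; the README shows the user-facing workflow.

## 1. The phantom: shared ground truth

Every quantity the comparison operates on lives on a bull's-eye grid of 8
apico-basal slices × 32 wall sectors. The phantom therefore models the LV
directly in those shell coordinates rather than as a meshed 3-D chamber:
each (slice, sector) cell carries a wall thickness (default 10 mm) and a
scar **transmurality** `T ∈ [0, 1]` — the fraction of the wall, measured
from the endocardium outward, occupied by scar. Shell coordinates preserve
exactly the wall-depth structure that both pipelines measure while removing
meshing and registration complexity; both modalities are generated in the
same frame, so apex and axis are shared by construction and no image
registration is needed.

**Geometry.** Endocardial radius tapers linearly from 25 mm at the base to
19 mm at the apex; with the 10 mm wall and 8 mm slice thickness the shell
encloses ≈ 105 mL of myocardium — the scale of an adult pig or human LV
(≈ 110 g). These radii also set the in-plane size of the rendered
short-axis images and hence how many voxels sample each sector wedge.

**Infarct shape.** Cells are ranked by an elliptical distance (sector axis
2.2× the slice axis, seeded jitter of centre and axis ratio for
between-subject variability) from an anteroapical centre. The closest
`infarct_fraction` of all cells (rounded to the nearest cell) forms the scar
support — a single connected anteroapical region with apical involvement.
The shape family is a modelling choice; no shape statistics beyond location
are available to emulate.

**Transmurality profile.** Within the support, `T` decays from `t_peak`
(0.95) at the centre to `t_edge` (0.12) at the rim along a *single smooth
power law* `T(d) = t_peak − (t_peak − t_edge)·(d/d_edge)^γ`, with γ solved
so that exactly `core_fraction` of the support lies above `T = 0.75`. Two
details matter:

* A two-piece profile hinged at 0.75 would concentrate cell density at the
  very threshold the calibration operations try to recover — a confound
  that makes threshold estimates noise-dominated. The power law keeps the
  density of `T` values smooth through all the diagnostic cut-offs while
  still honouring the exact core-count constraint.
* `t_edge = 0.12` (≈ 1.2 mm of scar depth at default geometry) is the
  minimum involvement of any scar cell: sub-voxel scar rims are below the
  resolution of 1 mm imaging and are not modelled. This also makes the
  scar support of a noise-free rendering exactly recoverable.

With the default `infarct_fraction = 0.36` and `core_fraction = 0.5`, the
derived quantities land in the range reported for chronic reperfused LAD
infarcts: ≈ 20 % of myocardial volume, a transmural (BiPV < 0.8 mV) surface
area near 13 %, and a combined infarcted surface near 26 %.

## 2. The voltage model

Bipolar voltage is piecewise-linear in transmurality and **anchored at the
two standard bipolar cut-offs**: `BiPV(0.75) = 0.8 mV` and
`BiPV(0.25) = 1.9 mV`, extended linearly (2.45 mV at `T = 0`, 0.25 mV at
`T = 1`) and clipped to `[0.05, 3]` mV. The anchoring makes the printed
cut-off table the exact noise-free truth, so the calibration sweep has a
known recoverable answer (0.80 mV at the 75 % level) and the 25 % level's
answer (1.9 mV) deliberately falls outside the swept 0.5–1.5 mV range,
exercising the saturation path.

Unipolar voltage summates surrounding tissue, so it responds to the **scar
burden**: `T` averaged over a 3 × 3 cell neighbourhood (radius
configurable). Healthy cells sit at a 17 mV plateau; any cell with scar
drops onto `13.5 − 10·burden` mV. The deliberate gap between the plateau
(17) and the top of the scar line (13.5) around the 15 mV cut-off keeps
sparse-sample interpolation from flipping classifications at the infarct
rim: a cell's interpolated value would need a pull of > 1.5 mV to cross the
band edge. It also makes the unipolar "core + border" area equal the scar
support exactly in the noise-free limit — the conservation property the
tests assert. Sampled voltages get independent Gaussian noise
(`noise_sd_mV`, default 0 in the model, 0.1 in cohort runs) and are
truncated at zero.

## 3. MRI rendering and the 2SD rule

Each slice is rasterised at `voxel_mm` (default 1 mm) in-plane resolution;
a voxel is myocardium if its centre radius lies in `[r_endo, r_epi)` and
scar if additionally its depth `r − r_endo` is at most `T·wall` of its own
sector. Intensities are `N(100, 10)` for normal myocardium and `N(160, 10)`
for scar (arbitrary units) — comfortably separable by the 2SD rule, which
needs `scar mean > normal mean + 2·SD`. The **remote region** (the
segmentation reference) is the myocardium of cells whose whole 3 × 3
neighbourhood is scar-free, so the reference never touches the infarct rim.

`segment_2sd()` tags myocardial voxels strictly greater than
`mean + 2·sd` (sample SD) of the remote voxels. Under Gaussian noise this
rule has an irreducible ≈ 2.3 % false-positive floor in normal myocardium;
at default conditions that yields a voxel Dice of ≈ 0.95–0.96 against the
ground-truth scar and inflates the infarct volume by ≈ 2 percentage
points — the behaviour of the strict rule, reported as such rather than
post-processed away. A uniform stack yields an empty mask (threshold equals
the constant); only a remote region with fewer than 2 voxels is an error.

## 4. Transmurality by midline radial projection

For each (slice, sector) wedge around the slice's myocardial centroid the
package measures the radial extent of scar as a fraction of wall thickness.
Two constructions are provided:

* **`method = "boundary"` (default).** The endocardial, scar and epicardial
  boundary radii of the wedge are localised at *sub-voxel* precision: the
  voxel centres of a wedge sample the radius at ≈ 0.25 mm spacing (oblique
  centres fall between integer radii), so each boundary is taken as the
  midpoint between the outermost radius inside it and the innermost radius
  beyond it. The scar boundary uses the *minimum-misclassification* cut
  (fewest voxels on the wrong side), which reduces to the clean gap
  midpoint on noise-free data and is robust to the isolated 2SD
  false-positive voxels — a stray tagged voxel mid-wall cannot drag the
  boundary outward. Endo/epicardial radii, which belong to anatomically
  smooth closed contours, are additionally smoothed circumferentially over
  ± 2 sectors; the scar boundary is never smoothed, because it carries the
  signal. A wedge entirely scar is exactly 1; entirely clean, exactly 0.
* **`method = "ray"`.** The literal construction: a fan of rays through the
  wedge (one ray = the exact midline), nearest-voxel sampled at 0.1 voxel
  radially, transmurality = scar samples / myocardial samples pooled over
  the fan. This is exact on analytic half- and full-thickness sectors with
  lattice-aligned midlines (the tests assert 0.5 and 1.0 exactly), but on
  realistic geometry its quantisation error along nearly parallel rays is
  larger than the boundary method's.

The boundary method is the default because correlated-ray quantisation at
1 mm voxels cannot reliably meet a 0.05 recovery bound in the small apical
wedges, while sub-voxel boundary localisation can: on noise-free rendered
phantoms the maximum cell error is ≈ 0.04 and the recovered scar support
matches the phantom's exactly. Each anatomical slice is rendered and
analysed as one voxel layer (the 8 mm slice thickness enters volumes, not
the projection), so the question of aggregating multiple layers within a
slice does not arise; the layer is the slice mean by construction.

## 5. Classification bands

Printed strict inequalities are honoured and boundary values land in the
middle band; all bands partition their domain without gaps:

| map | bands |
|---|---|
| unipolar | infarct `< 5`, border `[5, 15]`, normal `> 15` mV |
| bipolar | transmural `< 0.8`, non-transmural `[0.8, 1.9]`, normal `> 1.9` mV |
| SI 25-50-75 | normal `[0, 25)`, non-transmural `[25, 50]`, border `(50, 75]`, transmural `(75, 100]` % |
| SI 30-60 | normal `[0, 30]`, non-transmural `(30, 60]`, transmural `(60, 100]` % |

The 30/60 scheme is printed ambiguously at the value 30 ("<30" in one
place, "31–60" in another); assigning 30 to the normal band is this
package's documented interpretation. Area fractions are always the
percentage of *valid cells* carrying a class on the raw 8 × 32 grid — the
interpolated, smoothed disk raster exists for display and RGB round-trips
only and never enters a quantitative result.

## 6. Polar maps from sparse points

Mapping points (positions on the endocardial shell plus bull's-eye
coordinates, apex at the centre) are interpolated to the cell centres by
inverse-distance weighting (power 2) using only points within the 15 mm
point-connection distance; a cell reached by exactly one point takes that
point's value, a point coinciding with a cell centre supplies its value
exactly, and unreached cells are invalid. Only `stable` points participate.
The outer 8 % of the disk radius is the fibrous ring / valve plane and is
always invalid (the width is a convention; the exclusion itself is standard
practice because the annulus carries artifactually low voltages). With the
default 202 points (≥ 4 per 12-segment region) every cell of the 8 × 32
grid is within reach; one point per cell ("dense" sampling) reproduces the
model fields exactly and serves as the idealised limit in the
self-consistency tests.

## 7. Threshold calibration, ROC, and agreement statistics

**Sweep.** For thresholds `t` in 100 steps of 0.01 mV from 0.5 to 1.5, the
area `{BiPV < t}` (restricted to the MRI-defined infarct crop, as % of the
valid surface) is computed per subject and correlated across the cohort
with the MRI area above each transmurality level; the `t` maximising the
correlation is the calibrated cut-off for that level. Cohort-level area
correlation (rather than pooled pixel correlation) is the reading adopted
for "correlation between the two images"; the pooled-pixel alternative
would conflate within- and between-subject variation. A maximum on or
within one step of a sweep boundary is reported as the boundary value and
flagged `saturated` — it is not an interior optimum, and the 25 % level is
expected to saturate by construction. Degenerate sweeps (area constant in
`t` for every subject, or fewer than 3 subjects) are errors, not numbers.

**ROC.** Points are labelled non-viable by `UPV < 5 mV`; BiPV is the score
(lower = more likely non-viable; positive call `BiPV < c`). The AUC is
trapezoidal (identical to the Mann–Whitney rank form, which the bootstrap
uses for speed); the 95 % CI is a seeded 2000-resample percentile
bootstrap, the CI method being this package's choice. Single-class input is
an error.

**Overlap.** On the shared grid the two overlay areas `c` and `d` of the
`(c+d)/(a+b)` statistic both equal the intersection, so the ratio *is* the
Dice coefficient; the implementation computes it on the shared grid and the
tests assert equality with an independent Dice computation to 1e-12.
Grades: good > 0.60, moderate 0.50–0.60, else poor (conventional,
configurable). An empty region pair gives `NA` with an explicit
"undefined" grade and a warning, never a silent number.

**Regression and Bland–Altman.** The least-absolute-residual line is fitted
by IRLS with weights `1/max(|r|, 1e-8)`, a 200-iteration cap and a 1e-10
step tolerance; the loss is prescribed, the algorithm is this package's
choice. Because the L1 optimum sits at a kink, the step criterion may stall
near 1e-8 on noisy data — non-convergence is signalled with the last step
size while the returned line is still optimal to well below measurement
precision (the tests verify optimality against a brute-force grid search).
Bland–Altman differences are `NOGA − cMRI` (positive = voltage map
overestimates), limits exactly `mean ± 2·SD`; since "± SD" notation is
ambiguous between the SD of differences and the limit half-width, both are
reported.

## 8. Cohorts, seeds and problem sizes

`run_cohort()` drives the full experiment from one `cohort_config`: a
master seed expands into per-subject seeds, each subject draws
`infarct_fraction` and `core_fraction` uniformly from configured ranges
(defaults 0.15–0.45 and 0.3–0.6), and the per-subject tables, agreement
statistics, sweep and pooled ROC are assembled; identical config + seed
gives byte-identical CSV/JSON outputs, and the JSON report records package
version, configuration and all subject seeds. A failed subject is recorded
and skipped, not fatal. Test and acceptance runs use 30–60 subjects at
1 mm voxels — a cohort renders and analyses in seconds, and the sizes are
chosen so cohort statistics (correlations, overlap means) are stable to
well within the asserted margins.

## 9. What the phantom does and does not establish

Passing the self-consistency suite shows that the two measurement chains
are mutually consistent implementations of their definitions: noise-free,
densely sampled cohorts give `r = 1.0` and zero Bland–Altman bias between
the unipolar infarct extent and the MRI late-enhancement area, per-subject
combined overlap > 0.95, and exact recovery of the 0.8 mV anchor by the
sweep. Realistic noise and 202-point sampling then degrade agreement the
way real modality comparisons do (sparse interpolation smooths the
transmural core; the strict 2SD rule inflates volumes slightly).

The phantom does **not** emulate: registration error between truly
independent acquisitions (both modalities share one frame here);
catheter-coverage gaps, unstable contact points, or fibrous-ring voltage
artifacts beyond a mask; patchy or intramural/epicardial scar (scar is
radially nested from the endocardium); inversion-recovery physics,
partial-volume intensities or through-plane motion; and per-cell voltage
heterogeneity (voltages are cell-wise constants plus noise). Agreement
numbers from realistic-noise phantom cohorts therefore characterise the
pipeline, not animal or patient data, and should be read as
self-consistency diagnostics.
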