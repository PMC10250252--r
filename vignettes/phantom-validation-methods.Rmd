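---
title: "Validating coronary segmentation masks with phantom QCA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating coronary segmentation masks with phantom QCA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomQCA)
```

## The problem this package addresses

Automatic segmentation of coronary X-ray angiograms is usually validated in
two complementary ways: by pixel-overlap statistics against a reference
segmentation, and by clinically meaningful caliper measurements — vessel
diameters and percent diameter stenosis — taken with quantitative coronary
analysis (QCA) software and then re-measured on the model's output by
superimposing the QCA marker lines. Patient angiograms and trained networks
are rarely shareable, so the *measurement layer* of such a validation (the
part that turns two masks and a marker file into diameters, overlap metrics
and paired statistics) is hard to exercise, audit, and reuse.

`phantomQCA` implements that measurement layer exactly, and pairs it with a
synthetic phantom generator that plays the roles of the patient image, the
QCA workstation, and the imperfect segmentation model. Because the phantom's
geometry is analytic, every measurement has a known ground truth, and the
whole validation study — generation, degradation, caliper measurement,
overlap, statistics, reporting — can be run and checked end to end on a
desktop.

## The phantom model

A phantom is a 2-D label mask (0 background, 1 coronary, 2 catheter) built
from an analytic vessel tree:

* the main vessel follows a natural-spline centerline through control
  points; its local diameter tapers linearly with arc length,
  $d(s) = d_0\,(1 - \tau s)$, with $d_0$ the baseline diameter (mm) and
  $\tau$ the taper rate (fraction of diameter lost per mm);
* a focal stenosis multiplies the diameter by a raised-cosine notch that
  reaches $1 - \text{severity}$ at the lesion centre over a configurable
  lesion length. The smooth profile avoids rasterization artifacts exactly
  at the marker positions, where measurements are taken, and makes the
  analytic truth trivially exact: percent stenosis equals severity × 100 by
  construction;
* side branches attach at an arc position with a diameter fraction of the
  local parent caliber and taper along their own arc;
* the catheter is a constant-diameter tube (French size / 3 mm) entering
  from the image border and engaging the vessel origin.

Rasterization follows a single coordinate convention used everywhere:
0-based `(row, col)` with pixel centres at integer coordinates; a pixel
belongs to a class when its centre lies inside the analytic tube (realized
as a union of disks along a densely sampled centerline, 0.25 px steps).
For a straight, untapered vessel of diameter $d$ px this reproduces the
analytic width within ±1 px, the inherent quantization of a binary mask —
which is also the package's measurement resolution limit, discussed below.

The QCA reference record emulates what a validated workstation exports:
three marker lines perpendicular to the centerline at the proximal border,
lesion centre and distal border; the interpolated healthy ("reference")
diameter at the lesion; calibration in mm/pixel; and two parallel caliper
lines laid along the catheter edges, as automatic border detection draws
them. Marker half-length is 1.5 × the local healthy diameter, so the chord
search can never be truncated by a short marker. The workstation convention
for marker length and orientation is not documented publicly;
perpendicular-to-centerline is assumed and stated here once.

### Default study conditions

The generator's defaults define the cohort the synthetic study emulates and
were chosen once, on clinical grounds:

| parameter | default | rationale |
|---|---|---|
| canvas | 512 × 512 px | a standard acquisition matrix |
| pixel spacing | 0.1 mm/px | fine end of clinical detector spacing; a 3 mm vessel spans ~30 px, as in magnified QCA acquisitions |
| baseline diameter | 2.7–3.3 mm | proximal epicardial caliber |
| taper rate | 0.006–0.01 /mm | proximal-to-distal caliber loss over a ~45 mm segment |
| lesion length | 8 mm | a typical focal lesion |
| severity strata | 18% ≥70%, 47% 50–69%, 35% <50% | the severity mix of a QCA-regraded "visual 50–99%" cohort |
| catheter | 5 or 6 Fr | the two standard diagnostic sizes |

Severity is accepted down to 0.3 because visual 50–99% lesions regrade
below 50% by QCA in about a third of cases; severity 0 is kept as a
degenerate identity case for testing.

## The degradation operator

The simulated "model prediction" applies the characteristic defect profile
of automatic coronary segmentation, each defect drawing from its own RNG
sub-stream so toggling one leaves the others unchanged:

1. **Boundary bias + jitter.** A systematic signed displacement (px) and a
   random displacement field are applied in a single operation: the new
   coronary set is $\{p : \mathrm{sdf}(p) - b + \sigma Z(p) < 0\}$, where
   `sdf` is the signed distance to the coronary boundary and $Z$ is a
   seed-fixed, spatially correlated (2 px) unit-variance Gaussian field.
   With $\sigma = 0$ this is exactly morphological grow/shrink by $b$;
   with $\sigma > 0$ it is coherent boundary jitter around the displaced
   boundary. Two numerical properties follow: a binary mask cannot express
   $|b| < 0.5$ px without jitter (the field is half-integer at the
   boundary), and for a fixed seed each pixel crosses its threshold exactly
   once as $\sigma$ grows, so realized Dice is monotone in $\sigma$ — which
   makes calibration (below) a well-posed bisection.
2. **Collateral gaps.** Per branch, with the configured probability, a run
   of the configured length is erased at a random arc position in the
   distal half of the branch — where such gaps occur in practice.
3. **Catheter gap.** With the configured probability, catheter pixels are
   erased over a window ending just proximal of the tip, emulating contrast
   backflow obscuring the catheter where it meets the vessel.
4. **False-positive blobs.** A Poisson number of small disks is stamped on
   background at least one blob-diameter clear of any true foreground.

`calibrateToDice()` bisects the jitter $\sigma$ (all other defects from a
template) until the realized whole-image coronary Dice hits a target within
±0.02, erroring — with the best realized value named — when the template's
mandatory defects make the target unreachable.

## The caliper

`chordLength()` samples a marker line every 0.1 px; a sample is in-class
when its nearest pixel carries the class. The chord is the contiguous
in-class run containing the sample nearest the line midpoint; if the
midpoint sample is out-of-class, the nearest run within 2 px is used
(markers sit slightly off-centre on degraded masks), and failing that a
*gap* is signalled. The rule is deliberate: summing disjoint runs would
silently bridge segmentation gaps and overestimate diameters, whereas a gap
signal maps to an explicit case exclusion, mirroring how gap cases are
dropped from a clinical validation rather than imputed. The 0.1 px step
bounds sampling error at ~0.01 mm for typical spacing, far below the
smallest differences of interest (~0.1 mm); the dominant error is the ±1 px
mask quantization, i.e. ~0.1 mm at default spacing, or a few stenosis
points for a ~25 px reference vessel. That is why parameter-recovery
guarantees are stated for vessels ≥ 10 px wide.

Percent stenosis uses the QCA formula
$(\mathrm{ref} - \mathrm{lesion})/\mathrm{ref} \times 100$ with the
*reference* diameter taken from the QCA record, never re-derived from the
segmented mask (the segmented image contains no healthy-profile
interpolation to measure). A lesion chord wider than the reference yields a
negative stenosis, reported as-is — clamping would bias the paired
statistics. The catheter is measured either from the reference record
(perpendicular distance between the two edge-parallel caliper lines ×
calibration) or on the mask (catheter-class chord along a probe
perpendicular to and midway between them); caliper lines must be parallel
within 2°. Measuring the catheter also closes the calibration loop:
`calibrationFromCatheter()` recovers mm/px from a known French size, the
fallback used clinically when DICOM calibration metadata is absent. Only
isotropic spacing is supported; anisotropic inputs are out of scope.

## Overlap metrics and the region of interest

Pixels are classified TP/FP/TN/FN for the coronary class (per-class
computation is available via the `class_label` argument) and the seven
standard metrics are derived exactly as conventionally defined: accuracy,
sensitivity, specificity, PPV, NPV, IoU and Dice. A metric with a zero
denominator is *undefined* — reported as `NA` with a warning, never as 0 —
and propagates as missing into statistics. Dice = 2·IoU/(1+IoU) holds
algebraically and is asserted per case by the study audit.

The exact ROI a clinical workstation analysis used is generally unknowable;
the package makes both options first-class: the default ROI is the marker
bounding box padded by 10 px, and whole-image computation (used by the Dice
calibration) is a `roi = NULL` away. Enlarging the ROI only adds
background, which is why accuracy, specificity and NPV saturate toward 100%
as the ROI grows — metrics ignoring true negatives (sensitivity, PPV, IoU,
Dice) are the informative ones.

## The Global Segmentation Score

The GSS is a 0–100 expert rubric scored by consensus; the rating itself is
human work and is not automated here. The module validates rubrics (points
summing to exactly 100, unique criteria), records assessments, and
aggregates them as medians with interquartile ranges. The shipped example
rubric (main-vessel completeness 45, collateral continuity 25, catheter
continuity 20, artifact burden 10) reflects the qualities raters examine
but its weights are placeholders, fully replaceable via configuration — the
canonical allocation is not published in a reusable form. Collimation can
hide the catheter: such cases are flagged catheter-unscorable and are
excluded from totals and catheter-criterion summaries while still
contributing to the other criteria. Consensus is stored as a single
assessment row, not computed from rater rows.

## Statistics

* Normality gating uses Shapiro–Wilk at α = 0.05 (the convention-setting
  software names no test; this is the package's documented choice), with
  constant vectors reported as degenerate rather than crashing.
* Paired original-vs-segmented comparisons use the paired t-test when the
  paired differences pass normality and the Wilcoxon signed-rank test
  otherwise (the non-normal paired fallback is likewise a documented
  decision). All-zero differences report p = 1 with a degeneracy flag.
* Grouped comparisons use Mann–Whitney for two groups and Kruskal–Wallis
  for more.
* Quantiles are type 6 (SPSS-style linear interpolation of order
  statistics) everywhere, matching the reporting conventions of clinical
  statistics software.
* Difference columns summarize the *absolute* per-case differences — the
  convention implied by published IQRs starting at 0 — and this is stated
  in the report itself.
* No multiple-testing correction is applied, matching standard practice in
  this literature; p < 0.05 is the significance threshold.

## The study pipeline

`runStudy()` draws a randomized tree, severity (stratified), lesion
position, and defect realization per case from per-case seeds derived from
one root seed, so a study is bit-reproducible, case by case. The "original
image" arm uses the *analytic* truth diameters as the workstation stand-in;
caliper-on-truth is kept as a consistency column. This separates the
measurement error of the method under test from the phantom's own
rasterization error — comparing caliper-on-prediction to caliper-on-truth
would let rasterization bias cancel and overstate agreement. When a target
Dice is configured, the degradation is calibrated once, on the first case,
and the calibrated spec is applied to every case: a segmentation model has
one characteristic quality level, and per-case recalibration would model
something else (and triple the runtime). Vessel-marker gaps exclude a case
from all statistics; catheter gaps exclude only the catheter sub-analysis
(analysed separately for 5 Fr and 6 Fr, since pooling the two sizes makes
the sample bimodal). Every stage error is recorded per case without
aborting the study, and `auditStudy()` re-verifies the flowchart
reconciliation (generated = included + excluded with per-reason counts),
exclusion propagation into the statistics sample, ROI count completeness,
and the per-case Dice–IoU identity.

## What the phantoms do and do not establish

The phantoms emulate label-mask geometry, not X-ray appearance: there is no
gray-scale contrast, background anatomy, vessel overlap or foreshortening,
no motion blur, and no collimation (so the catheter sub-study's
"collimation" exclusion channel never fires synthetically — only gap
exclusions occur). Passing tests therefore establish that the measurement
layer is correct and unbiased at the stated resolution, and that the
pipeline's statistics behave nominally — not that any particular
segmentation model performs well on patients. Conversely, because the
ground truth is analytic, the phantom study can detect measurement-layer
biases (e.g. the chord rule's behaviour on jittered boundaries) that a
real-data validation cannot separate from model error.

## Problem sizes used by the test suite

The package's own test suite runs the full study at its default size
(120 cases, 512 × 512), the stenosis-recovery check on 100 phantoms with
severity 0.5–0.9, the Dice calibration check at three targets × 20 seeds on
320 × 320 phantoms, overlap-oracle equivalence on 200 random 32 × 32 mask
pairs, and the paired test's type-I behaviour over 1000 simulated null
studies; smaller canvases (256 × 256) are used where geometry, not
statistics, is under test.
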