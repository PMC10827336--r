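---
title: "Speckle-contrast perfusion imaging with automatic ROI tracking: models and methods"
author: "lascaTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle-contrast perfusion imaging with automatic ROI tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lascaTrack)
```

## The measurement problem

Laser speckle contrast analysis (LASCA) converts raw coherent-light images
of tissue into maps of relative blood flow. When red blood cells move
during the camera exposure, the interference pattern blurs; the local
speckle contrast

$$K = \frac{\sigma}{\langle I \rangle}$$

(standard deviation over mean of the intensity in a small window) drops
from 1 (static, fully developed speckle) towards 0 (fast flow). The
relative flow index $1/K^2$ is proportional to flow speed and is reported
in arbitrary units (AU); no absolute calibration in mm/s is attempted, so
an AU scale factor is exposed as configuration.

Perfusion is quantified inside a region of interest (ROI) drawn over a
lesion. Patients cannot hold wounded limbs still, so a fixed ROI drifts
off the lesion and corrupts the perfusion trace. This package implements
the remedy studied in wound-imaging practice: a discriminative correlation
filter (DCF) tracker with spatial and channel reliability follows the
ROI's circumscribed bounding box across frames, and the ROI is
repositioned whenever the tracked displacement exceeds a threshold.
Agreement between the automatically tracked trace and a reference trace
with perfect per-frame repositioning is quantified with the two-way random
intraclass correlation coefficient (ICC).

## Speckle contrast computation

`spatialContrast()` computes $K$ per pixel over a `window` x `window`
neighbourhood. Decisions a user should know:

* **Population standard deviation.** $K$ is an ensemble definition; the
  population form keeps the brute-force oracle in the test suite exact and
  makes constant regions give $K = 0$ exactly.
* **Window default 7 x 7** — common LASCA practice, trading spatial
  resolution against estimator variance. The window is a parameter
  everywhere; the segmentation example below uses 11 x 11, where
  resolution matters less than separation.
* **Borders.** Edge-inclusive symmetric reflection padding, so the output
  has the input's shape and border ROIs remain analyzable.
* **Dark pixels.** Windows with zero mean define $K = 0$; the flow index
  clamps $K$ at `kFloor` (default $10^{-3}$) before inverting, keeping
  $1/K^2$ finite.
* **Windowed estimator bias.** A 7 x 7 window holds ~49 correlated
  samples, so the *windowed* $K$ of static speckle averages ≈ 0.8–0.9
  rather than 1; the *global* contrast of a static frame is 1.00 ± 0.05.
  Tests that compare temporal against spatial estimates match the two
  estimators' effective sample counts (temporal depth 25 against a 13 x 13
  spatial window at grain 1 px) — both are then within 5% of each other,
  which is the ergodicity property the simulator is designed to have.

`segmentBackground()` exploits the contrast gap between static background
(a light-absorbing cloth keeps its fully developed speckle, windowed
$K \approx 0.8$–1) and perfused tissue ($K \approx 0.3$) with a plain
threshold (default 0.6). Within half a contrast window of the
tissue/background boundary the estimate mixes both regions, so quality is
judged on region interiors.

## ROI geometry

ROIs are circles or simple polygons in 0-based pixel coordinates
(x = column, y = row, pixel centers at integers). Membership is
boundary-inclusive: a pixel belongs to the mask when its center satisfies
$(p_x-c_x)^2+(p_y-c_y)^2 \le r^2$ (circle) or the even-odd rule (polygon).
Areas are analytic (circle $\pi r^2$, polygon shoelace) scaled by
`pixelScaleCm`$^2$; at the package's reference scale of 40 px/cm a
1-cm-diameter circle measures 0.785 cm² and a 1 x 2 cm rectangle 2 cm².

Two consequences of these conventions matter in practice:

* **Sub-pixel ROI positions.** The tracker produces real-valued centers;
  ROIs are re-rasterized from the exact geometry every frame, so repeated
  translation accumulates no rounding error.
* **Integer-position rasterization edge.** At exactly integer positions a
  boundary-inclusive rectangle of width $w$ covers $w+1$ pixel columns,
  while at generic sub-pixel positions it covers $w$. A reference ROI
  sitting on integer ground-truth positions therefore reads a slightly
  different pixel set than a tracked sub-pixel ROI — a small systematic
  trace offset of order (perimeter/area) x local intensity gradient. This
  is an inherent property of pixel-center rasterization, visible in the
  agreement analysis as a rater offset that absolute-agreement ICC
  correctly penalizes.

## The correlation-filter tracker

`initTracker()` learns per-channel correlation filters on the first
frame's template patch (the ROI's circumscribed bounding box padded 2x);
`trackStep()` locates the channel-weighted correlation-response maximum,
refines it to sub-pixel precision by a quadratic fit, moves the bounding
box and updates the model. Feature channels for monochrome speckle are
normalized intensity, gradient magnitude and four orientation-binned
gradient channels. The bounding-box size is fixed for the whole run — no
scale or rotation adaptation.

Design choices that required decisions:

* **Spatial reliability constrains training only.** The foreground mask
  (intensity-histogram Bayes classifier of bbox interior vs. padding ring,
  binarized, largest connected component, fallback to the bbox when
  coverage drops below 25% of the bbox area) multiplies the *training*
  features. Applying it to the detection features as well would anchor the
  response to the previous target position, because the mask itself does
  not move with the target.
* **Self-response origin calibration.** Training under the mask while
  detecting without it leaves the filter's self-response peak a fraction
  of a pixel off the template center. That offset is measured on the
  training patch (and re-measured after every model update) and subtracted
  from all displacement estimates; without it the tracker drifts by the
  bias once per frame.
* **Scale-relative regularization.** The ridge term is
  $\lambda \cdot \overline{|F|^2}$ per channel, making the filter
  invariant to intensity scaling of the input.
* **Channel reliability** is the peak-to-sidelobe ratio of each channel's
  response, blended by an exponential moving average (rate 0.2) and
  normalized to sum to 1. Raw peak height is a poor quality measure — a
  channel can produce a tall but position-ambiguous response.
* **Search radius 10 px per frame** (configurable). DCF trackers restrict
  the admissible displacement to a search region; 10 px/frame (2.5 mm at
  40 px/cm) covers deliberate limb repositioning while making genuinely
  fast motion fail the way it fails in practice: the tracker lags, then
  loses the target.
* **Displacement threshold 1 px.** The tracked box jitters by fractions
  of a pixel on stationary targets; updating the ROI only when the
  frame-to-frame displacement exceeds 1 px (Euclidean) makes the ROI
  trajectory exactly constant under sub-threshold jitter.
* **Lost-target policy.** A response peak below 0.2x the training-frame
  peak flags the frame and holds the box, rather than silently locking
  onto background.
* **Tracking input.** By default the tracker runs on the contrast image
  (the lesion is visible there, and contrast is computed before tracking
  in the per-frame pipeline); tracking on the raw frame is a config
  switch.

Standard settings (learning rate 0.02, $\lambda$ = 0.01, cosine window,
Gaussian target with $\sigma = \sqrt{wh}/16$) are all exposed in
`trackerConfig()`.

## Dynamic-speckle simulator

`simulateSequence()` provides ground truth for every downstream module
without acquisition hardware. The forward model:

* **Fully developed speckle**: circularly symmetric complex Gaussian
  fields, low-pass filtered to a grain scale (default 1.5 px) and
  normalized — pointwise intensity is exactly exponential, so static
  scenes have global contrast 1.
* **Flow as decorrelation**: each region's field evolves between substeps
  as an AR(1) process on the *complex field* (not the intensity),
  $f' = \rho f + \sqrt{1-\rho^2}\,w$ with $\rho = e^{-1/\tau}$, which
  preserves fully developed single-frame statistics exactly. Shorter
  $\tau$ = faster flow.
* **Exposure blur**: a frame is the mean of M consecutive substep
  intensities (default M = 8), so contrast falls monotonically as
  $\tau$ shrinks or M grows.
* **Scene**: perfused tissue (default $\tau = 0.5$ substeps) inside a
  tissue rectangle; occluding lesion patches (default $\tau = 10^8$,
  effectively static — the analogue of adhesive opaque patches taped to
  skin to block flow) composited on top; static low-intensity cloth
  outside. Geometry maps to physical units at 40 px/cm, consistent with a
  ~20 x 15 cm field on a 1280 x 1024 sensor.
* **Motion**: a per-frame rigid offset of the whole scene (bilinear
  interpolation, border-clamped; bilinear rather than spectral shifting
  avoids ringing on exponential-statistics images), with the lesion
  centers recorded per frame as ground truth.
* **Physiological variability**: the tissue decorrelation *rate* can be
  modulated sinusoidally across frames (`flowModAmplitude`,
  `flowModPeriodFrames`). Real perfusion signals vary severalfold over a
  recording; this temporal variance is exactly what the between-target
  component of the ICC measures, so the agreement scenarios enable it
  (amplitude 0.7) while the stationary statistical tests leave it off.
* **Digitization**: frames are quantized to 16-bit camera counts (gain
  65535/8 counts per unit mean intensity keeps clipping below $10^{-3}$
  of pixels), which also makes TIFF round-trips bit-identical.

Everything is deterministic under the configured seed.

What the simulator does *not* emulate: physically calibrated tissue
optics, camera noise beyond optional additive Gaussian read noise,
non-rigid deformation, rotation, out-of-plane motion, and illumination
inhomogeneity. Passing tests therefore demonstrate correctness of the
algorithms under rigid motion with ideal speckle statistics, not clinical
performance.

## Agreement analysis

`iccTwoWay()` implements the single-measure absolute-agreement two-way
random ICC — ICC(2,1) — from the two-way ANOVA mean squares:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},$$

which equals $\sigma_B^2 / (\sigma_B^2 + \sigma_W^2)$ with
$\sigma_B^2 = (MS_R - MS_E)/k$ the between-target (between-frame) variance
of interest and $\sigma_W^2$ aggregating rater and residual variance. The
"two-way random" label does not by itself fix the variant; single-measure
absolute agreement is the standard choice for method comparison and is
what is implemented (variance components are reported so other forms can
be assembled). Components are clamped at zero; the ICC itself is reported
unclamped, so agreement-free data can show small negative values.
Reliability bands follow the conventional cut points — below 0.5 poor,
0.5–0.75 moderate, 0.75–0.9 good, above 0.9 excellent — with boundary
values assigned to the upper band (0.75 is "good").

`runAgreementExperiment()` reproduces the validation protocol on
simulator output: the "manual" arm repositions the analysis ROI at its
ground-truth center in every frame (the idealization of an assessor
redrawing the ROI; real manual annotation is out of scope), the "auto"
arm places the ROI only in the first frame and tracks. Traces are paired
per frame (n = frames, k = 2 raters). The analysis ROI may include a
margin of tissue around the occluding patch (as a clinician would draw
around a wound); the margin is what couples the trace to the modulated
tissue perfusion.

Two reference scenarios fix the study conditions
(48 frames, 144 x 256 px):

* `slowScenario()` — a 1 x 2 cm rectangular patch centered in tissue,
  analysis ROI with a 0.2 cm margin, oscillating at 2 px/frame. Tracking
  follows to ~0.3 px; ICC lands in the excellent band.
* `fastScenario()` — a 1-cm circular patch at the tissue edge, half over
  dark cloth, sweeping at 15 px/frame (beyond the 10 px search radius).
  The tracker lags and loses the target, the ROI reads a wrong
  tissue/cloth mixture, and the ICC collapses — the fast-motion,
  small-target failure mode seen with fingertip ROIs over dark pads.

`movingAverage()` (centered, reflection at the ends, default window 5,
w = 1 = identity) suppresses instantaneous motion-artifact spikes in
exported traces; only the average filter is in scope.

## Problem sizes and runtime

The package's validation uses 144 x 256 px frames, 30–50 frame sequences
and three agreement runs of 48 frames each — sizes chosen so the full
suite and the acceptance script each complete in about a minute on a
single CPU while leaving every statistical check comfortable margins
(e.g. global contrast estimated from 65 536 pixels, ICC recovery from
n = 500 frame pairs averaged over 5 replicates).

## Known limitations

* Rigid translation only — rotation/scale-adaptive tracking is
  deliberately out of scope, matching the fixed-bbox design.
* The reference ("manual") arm is simulator ground truth, not a human
  assessor; inter-rater variability of real annotation is absent.
* The flow index is relative; comparisons across imaging sessions require
  a stable AU convention.
* The DCF tracker assumes the target stays partly inside the search
  region; occlusion handling is limited to the lost-target flag.
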