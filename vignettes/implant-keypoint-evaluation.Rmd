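---
title: "Evaluating implant landmark detectors: OKS, observer agreement and bone-loss grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating implant landmark detectors: OKS, observer agreement and bone-loss grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implanteval)
```

## The problem

A detector for dental implants on periapical radiographs produces, per
implant, a bounding box with a confidence score and six landmarks: the left
and right marginal bone levels, the left and right apex corners, and the
left and right implant top (the most coronal thread). Two questions follow.
How good are the landmarks — in particular, how do they compare with a
human annotator who provides no confidence scores? And what do the
landmarks imply clinically, i.e. how much marginal bone has been lost
around each implant? This package answers both from the detector's output
files alone; it contains no network and consumes any detector's
predictions.

## The similarity model

Box quality uses plain intersection over union. Landmark quality uses an
implant-specific object keypoint similarity: for implant $j$,

$$\mathrm{OKS}_j \;=\; \frac{\sum_i \exp\!\big(-d_{ji}^2 / (2 s_j^2 k_i^2)\big)\,\delta(v_{ji}>0)}{\sum_i \delta(v_{ji}>0)},$$

with $d_{ji}$ the Euclidean pixel displacement of keypoint $i$, $s_j$ the
implant scale (square root of the ground-truth segmented area — never the
box, which would conflate box error with keypoint error), $v_{ji}$ the
ground-truth visibility flag, and $k_i = 2\sigma_i$ the per-keypoint
tolerance. The model's assumptions are worth stating:

* displacement is penalized radially — no axis is privileged, so the
  implicit error model per keypoint is isotropic in the image plane;
* keypoints labeled but not visible ($v = 1$) still count: the indicator is
  $v > 0$, because an occluded landmark was nevertheless placed by the
  annotator and carries information;
* an implant with *no* labeled keypoint has an undefined OKS (0/0) and is
  excluded from every average; scoring it 0 would bias comparisons against
  whoever happened to meet such an implant.

The tolerances $\sigma_i$ are *measured*, not chosen: annotate a set twice
and estimate $\sigma_i^2 = \mathrm{E}_j[d_{ji}^2/s_j^2]$ over implants where
keypoint $i$ is labeled in both passes (`calibrate_sigma()`). The scale in
this estimate is taken from the first (reference) pass — the choice is a
convention, made deterministic here, and matters only at second order since
the two passes describe the same implant. The shipped default,

```{r}
default_sigma()
```

has bone-level entries about four times larger than the apex and top
entries. This is a real property of the task — the marginal bone level is
genuinely ambiguous on radiographs — and it has a known side effect: OKS
*under-weights* bone-level error relative to the landmarks that are easy to
place. A detector can be sloppy exactly where clinical interest is highest
and still score well. We keep the metric as defined (comparability with the
calibration is the point) and flag this as its main limitation.

The constant in $k_i = 2\sigma_i$ is exposed as `k_constant` (default 2)
but changing it changes the meaning of every downstream number; it exists
so that sensitivity can be examined, not as a tuning knob.

## The detection protocol

`evaluate()` follows the COCO-lineage protocol: predictions ranked by
descending score; per image, each prediction greedily claims the
highest-similarity unmatched ground truth at or above the threshold;
precision–recall over the score sweep; 101-point interpolated average
precision; AP/AR averaged over thresholds 0.50–0.95 step 0.05. Three
deliberate deviations from stock COCO:

* **No maximum-detections cap.** Radiographs hold a handful of implants;
  COCO's 20/100-detection caps would never bind and are dropped.
* **Selectable ranking score, defaulting to the keypoint score.** Box
  confidence reflects the box head, and empirically need not track keypoint
  quality; for keypoint PR curves the mean of the six per-keypoint
  confidences is the default ranking signal (`kp_aggregate = "max"` is
  offered). The box score remains available (`ranking = "box_score"`), and
  is what the cross-check against the reference protocol uses.
* **Ties.** Equal ranking scores are ordered by (image id, input order), so
  replays are deterministic; in the PR sweep equal scores enter together
  and collapse to one curve point.

Numerical conventions: the AP recall grid is `(0:100)/100`, and achieved
recall is compared against grid recall with a slack of 1e-10 — this guards
against double-precision artifacts (e.g. 3/10 falling a ULP short of the
grid's 0.3) and is applied identically in the test-suite oracle. AR at a
threshold is recall with every prediction retained (no score floor); with
no cap this equals maximum recall. Degenerate inputs: an image set with no
ground truth has undefined recall and is an error, not a silent 0.

## Observer agreement and its analytic reading

AP/AR need scores, and humans do not produce them. `mean_oks()` therefore
fixes a single detection threshold — box score strictly above 0.7 — matches
surviving predictions to ground truth one-to-one by highest OKS (ties by
prediction order), and averages. The report records the σ vector used;
`compare_observers()` (and the CLI `compare`) refuses to compare reports
computed under different tolerances, because mean OKS is only meaningful
relative to its calibration.

A mean OKS $q$ inverts analytically. If every labeled keypoint sat at the
same normalized displacement $d/s = m\,\sigma_i$, then
$q = \exp(-m^2/8)$, so $m = \sqrt{-8\ln q}$
(`oks_to_sigma_multiplier()`); at $q = 0.8885$, $m \approx 0.9725$. Under
the model in which the signed one-dimensional projection of human
annotation error, scaled by $s\,\sigma_i$, is standard normal, the share of
human annotations with smaller absolute deviation is $2\Phi(m)-1$
(`fraction_better()`); at $m = 0.9725$ this is $66.92\%$. That projection
model is adopted as the *definition* here: it is the unique reading under
which the multiplier and the percentile are consistent with each other.

One subtlety, verified in the tests: the inversion treats the displacement
as deterministic at multiplier $m$. If instead each axis is Gaussian with
SD $s\sigma_i m/\sqrt2$ (the generator's model, which makes
$\mathrm{E}[d^2/s^2] = m^2\sigma_i^2$ exact), then by the $\chi^2_2$
moment-generating function $\mathrm{E}[\mathrm{OKS}] = 1/(1+m^2/8)$, which
at $m = 0.9725$ is $0.8943$ — a Jensen gap of about $0.006$ above
$\exp(-m^2/8) = 0.8885$. The mean-OKS consistency test asserts both the
exact Gaussian expectation and proximity to the deterministic inversion at
the tolerance where both hold.

For two observers' OKS lists the package runs an independent two-sample
t-test, two-sided. Welch's unequal-variance form is the default — the safer
choice when one "observer" is a model whose error variance has no reason to
match a human's — with the pooled-variance Student form as an option. When
both lists are constant (e.g. two perfect observers), the statistic is 0/0;
the package reports $t=0, p=1$ for equal means rather than erroring.
Paired or nonparametric alternatives are out of scope by design: OKS lists
from different observers over different detection sets are not generally
pairable.

## Bone-loss measurement

The total implant length is the distance from the apex midpoint to the
implant-top midpoint; the defect length is the distance from the top
midpoint to the marginal bone-level midpoint; the bone-loss percentage is
their ratio. The implant top (most coronal thread) serves as the sound-bone
reference — a landmark identifiable on all implant types without a baseline
radiograph, at the cost of a known bias for tissue-level implants, which is
documented, not corrected. Severity: normal (≤10%), early (>10–≤25%),
moderate (>25–≤50%), severe (>50%); boundaries belong to the class on
their left, and `classify_severity()` probes this to ±1e-9 in the tests.

Two sign conventions are deliberate. The raw distances are unsigned, so a
bone level *coronal* to the top (bone gain, or projection artifact) would
masquerade as loss; the bone-level midpoint is therefore projected onto the
apex→top axis, and a non-positive projection clamps the defect to 0. At the
other end, a bone level apical to the apex midpoint yields >100%; the
percentage is clamped to 100 and flagged (`clamped = TRUE`) rather than
rejected — such radiographs exist. `defect ≤ total` is *not* asserted
anywhere. The percentage is invariant under rotation, translation and
uniform scaling of the six keypoints, which the property tests check; this
is what makes a pixel-space ratio clinically meaningful despite unknown
radiographic magnification. The absolute defect depth in millimeters is the
ratio times the implant's real (catalog) length, `absolute_bone_loss()`.

## What the synthetic generator does and does not emulate

`generate_ground_truth()` places implants as rotated rectangles (defaults:
length 150–300 px, width 45–80 px, tilt within ±15° of vertical on
1000×800 px images, 1–3 implants per image, half upper jaw). The six
keypoints derive exactly from the rectangle, with bone levels at a sampled
loss percentage along each side, so `measure_bone_loss()` recovers the
sampled percentage to machine precision — construction and measurement
close over the same geometry. The loss mixture defaults to
0.40/0.25/0.20/0.15 over normal/early/moderate/severe, a plausible clinic
mix with healthy cases most common; the severe bin is capped at 85% since
complete-loss radiographs are rare. `perturb_to_predictions()` displaces
keypoints with isotropic Gaussian noise at per-axis SD
$s\,\sigma_{\mathrm{true},i}/\sqrt2$ — the unique isotropic choice making
$\mathrm{E}[d^2/s^2] = \sigma_{\mathrm{true},i}^2$ exact, hence making σ
recovery a parameter-recovery problem with a known answer — and adds
misses, box jitter, and false positives with random geometry. Determinism
is strict: one random stream per image, keyed by (seed, image index,
operation), so enlarging a study never reshuffles earlier images, and the
caller's RNG state is untouched.

What this does *not* emulate: radiographic texture, graft material,
overlapping anatomy, annotator bias (the noise is zero-mean by
construction), visibility-flag heterogeneity (generated truth is all
$v=2$), or curation effects. Passing tests therefore demonstrate that the
*metrics and their inversions* behave as specified under the assumed error
model — not that any detector performs at any level on clinical images.

## Rendering

Keypoint-logit grids (a JSON tensor: height × width × 6 plus a region
origin) are normalized per channel by min–max to $[0,1]$ — min–max is
chosen over a sigmoid because it achieves the stated range exactly for
arbitrary logits; a sigmoid option exists for calibrated log-odds. A
constant channel maps to zeros, not 0.5: no signal should paint nothing.
Channels combine by per-pixel maximum and blend onto the radiograph with
intensity-scaled alpha under a perceptually uniform colormap (default
viridis), so zero-intensity pixels leave the image untouched. Annotated
prediction renders (box, keypoints, midpoints, the two measured segments,
and a text readout like `25.0% early (0.93)`) are pure array arithmetic
with an embedded 3×5 bitmap font — byte-identical across platforms, with
no font stack in the loop.

## Problem sizes and test design

The suite verifies σ recovery at 500 implants (within 10%) and 5000
implants (within 3% — the sampling SD of $\hat\sigma/\sigma$ at $n=5000$
is about 1%, so 3% is a 3-SD band); mean-OKS consistency over 1000
implants (within 0.01); protocol agreement with an independently coded
reference evaluator on 20 randomized small studies (within 1e-6 per cell);
OKS identities on 200+ randomized instances; and the t-test's type-I error
over 1000 replicates of two n=100 groups (rejection rate within 3–7% at
nominal 5%). These sizes keep each check's sampling error several times
smaller than its tolerance while completing in about a minute of total
test time.

## Known limitations

* OKS under-weights bone-level error (see above); a clinically weighted
  variant would need a new calibration and is future work.
* The mean-OKS comparison assumes both observers were scored under the same
  σ and the same matching rule; the report metadata enforces the former and
  records the latter.
* Bone-loss grading from a single radiograph cannot diagnose
  peri-implantitis — that requires clinical signs (bleeding, probing) and,
  ideally, baseline-radiograph differencing, both out of scope here.
* File ingestion covers the COCO-dialect JSON only; DICOM or raw pixel
  ingestion is deliberately excluded — images enter the package only as id,
  size and (for rendering) a generic raster.
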