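# implanteval

Keypoint-based evaluation of dental-implant detection on periapical
radiographs, and conversion of the detected landmarks into a radiographic
bone-loss percentage with a four-level peri-implantitis severity class.

## Who this is for

Groups building or validating landmark detectors for dental implants need
three things that generic object-detection tooling does not provide in one
place: (1) an implant-specific *object keypoint similarity* (OKS) whose
per-keypoint tolerances are calibrated from repeated expert annotation,
(2) a way to compare a detector against a human annotator — who emits no
confidence scores, so AP/AR cannot be used — and (3) the clinical readout:
how much marginal bone has been lost around each implant. `implanteval`
implements all three, plus a synthetic fixture generator so every part of
the pipeline is testable without clinical images.

## The metrics

Each implant instance carries six ordered landmarks: left/right marginal
bone level, left/right apex, left/right implant top (the most coronal
thread, used as the sound-bone reference). For implant *j* with
ground-truth keypoints *i*, detected keypoints at distance *d*ⱼᵢ, implant
scale *s*ⱼ = √(segmented area), visibility flags *v*ⱼᵢ and per-keypoint
tolerances *k*ᵢ = 2·σᵢ:

    OKS_j = Σᵢ exp(−d²ⱼᵢ / (2 s²ⱼ k²ᵢ)) · δ(vⱼᵢ > 0)  /  Σᵢ δ(vⱼᵢ > 0)

The σᵢ are the standard deviations of repeated human annotation, normalized
by implant scale, and are estimated from a twice-annotated set as
σᵢ² = E[d²ⱼᵢ / s²ⱼ] (`calibrate_sigma()`). The shipped calibration is

    σ = [0.0895, 0.0816, 0.0193, 0.0196, 0.0209, 0.0273]

in schema order — note the bone-level entries are ~4x larger than the
apex/top entries: the marginal bone level is the hardest landmark even for
a dentist.

Around the two similarity measures (OKS for keypoints, IoU for boxes) the
package implements the COCO-lineage protocol: greedy one-to-one matching by
descending score, precision–recall curves over the score sweep, 101-point
interpolated average precision, and AP/AR averaged over similarity
thresholds 0.50–0.95 in steps of 0.05 (`evaluate()`), reported pooled and
stratified by jaw.

For human comparison, `mean_oks()` averages OKS over implants detected with
box score above 0.7. A mean OKS *q* has an analytic reading: inverting the
single-keypoint similarity gives the equivalent displacement multiplier
*m* = √(−8 ln *q*) (in units of σᵢ·s), and under a standard-normal model of
scaled annotation error, 100·(2Φ(*m*)−1) percent of human annotations lie
closer to ground truth than the detector's equivalent displacement
(`oks_to_sigma_multiplier()`, `fraction_better()`). Two observers'
per-implant OKS lists are compared with an independent t-test
(`compare_observers()`, Welch by default).

Finally, `measure_bone_loss()` turns the six keypoints into the defect
ratio — distance from the implant-top midpoint to the bone-level midpoint,
over the apex-to-top midpoint distance — and classifies it: normal (≤10%),
early (>10–≤25%), moderate (>25–≤50%), severe (>50%).

## Worked example

```r
library(implanteval)

config <- synthetic_config(n_images = 50, seed = 42)
sb <- synthetic_bundle(config)           # truth + detector-like predictions
sb$truth
#> <dataset_bundle> 50 images, 104 implant annotations
#>   jaw: lower=28, upper=22

evaluate(sb$truth, sb$predictions, task = "keypoints")
#> <eval_summary> task=keypoints, ranking=keypoint_score, thresholds 0.50-0.95
#>     jaw ap_all  ap_50  ap_75 ar_all
#> 1   all 0.7193 0.9208 0.9208 0.7471
#> 2 lower 0.7332 0.9208 0.9208 0.7524
#> 3 upper 0.7016 0.9208 0.9208 0.7390

report <- mean_oks(sb$truth, sb$predictions)
report
#> <agreement_report> mean OKS 0.8804 over 96 matched implants (96 detections above 0.70)
round(oks_to_sigma_multiplier(report$mean_oks), 4)
#> [1] 1.0096
round(fraction_better(report$mean_oks), 2)
#> [1] 68.73

measure_bone_loss(sb$truth$annotations[[3]]$keypoints)
#> <bone_loss_measurement> 38.9% (moderate): defect 74.6 px of 191.7 px total
```

Reading: at the simulated noise level the detector's keypoints sit at about
1.01 human standard deviations from ground truth, so roughly 69% of human
annotations would be closer; AP(all) 0.72 over the OKS threshold grid; the
third implant has lost 38.9% of its length to the bone defect — a moderate
case.

Re-estimating σ from a second simulated annotation pass recovers the
shipped calibration:

```r
ra <- redundant_annotations(sb$truth, config)
calibrate_sigma(sb$truth$annotations, ra$second, ra$pairing)
#> <sigma_calibration> per-keypoint normalized annotation SD
#>  lt_bone_level  rt_bone_level   lt_apex   rt_apex  lt_implant_top  rt_implant_top
#>         0.0883         0.0832    0.0200    0.0203          0.0208          0.0266
```

## Command line

A thin wrapper around the same functions lives at `inst/cli/implanteval`:

```sh
Rscript inst/cli/implanteval simulate --out-dir fixtures --seed 17
Rscript inst/cli/implanteval evaluate --gt fixtures/gt.json \
    --pred fixtures/pred.json --task keypoints --out summary.csv
Rscript inst/cli/implanteval agreement --gt fixtures/gt.json \
    --pred fixtures/pred.json --out report.json
Rscript inst/cli/implanteval boneloss --pred fixtures/pred.json \
    --gt fixtures/gt.json --out boneloss.csv
```

Subcommands: `simulate`, `calibrate`, `evaluate`, `agreement`, `compare`,
`boneloss`, `heatmap`, `render`. Every artifact embeds a provenance header
(version, subcommand, seed, config hash) sufficient to re-run it.

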