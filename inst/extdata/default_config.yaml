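# Reference run configuration: the shipped per-keypoint sigma calibration
# (schema order: lt/rt bone level, lt/rt apex, lt/rt implant top), the OKS
# tolerance constant k = 2*sigma, the mean-OKS detection threshold and the
# similarity threshold grid.
sigma: [0.0895, 0.0816, 0.0193, 0.0196, 0.0209, 0.0273]
k_constant: 2
detection_threshold: 0.7
thresholds: [0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.95]
ranking: keypoint_score
severity_thresholds: [10, 25, 50]
severity_labels: [normal, early, moderate, severe]
seed: 1
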