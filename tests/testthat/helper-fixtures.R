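# Fixtures are built in code: a canonical vertical implant whose geometry is
# exact (width 20 px, length 200 px), so expected lengths, areas and OKS
# values have closed forms.

make_images <- function(n, jaw = rep(c("upper", "lower"), length.out = n)) {
  data.frame(image_id = seq_len(n), width = 1000, height = 800, jaw = jaw)
}

# vertical implant: top corners at y = 0, apex at y = len, bone level at
# fraction f of the length below the top
make_vertical_kp <- function(origin = c(100, 100), len = 200, wid = 20,
                             f = 0.25, v = rep(2L, 6L)) {
  x_l <- origin[1]
  x_r <- origin[1] + wid
  y_top <- origin[2]
  keypoints(
    x = c(x_l, x_r, x_l, x_r, x_l, x_r),
    y = c(
      y_top + f * len, y_top + f * len,
      y_top + len, y_top + len,
      y_top, y_top
    ),
    v = v
  )
}

make_ann <- function(id = 1L, image_id = 1L, origin = c(100, 100),
                     len = 200, wid = 20, f = 0.25, v = rep(2L, 6L)) {
  implant_annotation(
    annotation_id = id, image_id = image_id,
    bbox = c(origin[1], origin[2], wid, len),
    area = len * wid,
    keypoints = make_vertical_kp(origin, len, wid, f, v)
  )
}

make_pred <- function(ann, box_score = 0.9, kp_scores = rep(0.9, 6),
                      dx = 0, dy = 0) {
  kp <- ann$keypoints
  implant_prediction(
    image_id = ann$image_id,
    bbox = ann$bbox,
    box_score = box_score,
    keypoints = keypoints(kp[, "x"] + dx, kp[, "y"] + dy, kp[, "v"]),
    keypoint_scores = kp_scores
  )
}

make_bundle <- function(anns, n_images = max(vapply(anns, function(a) {
                          as.integer(a$image_id)
                        }, integer(1)))) {
  dataset_bundle(images = make_images(n_images), annotations = anns)
}

# a single OKS draw from the isotropic noise model at uniform multiplier m:
# each keypoint's exponent is (m^2 / 16) * chi-square(2)
simulate_oks_values <- function(n, m = 0.9725) {
  e <- matrix(stats::rchisq(n * 6L, df = 2), nrow = n)
  rowMeans(exp(-(m^2 / 16) * e))
}
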