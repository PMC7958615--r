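test_that("generation is deterministic and per-image streams are stable", {
  config <- synthetic_config(n_images = 5, seed = 11)
  a <- generate_ground_truth(config)
  b <- generate_ground_truth(config)
  expect_identical(
    lapply(a$annotations, unclass),
    lapply(b$annotations, unclass)
  )
  expect_identical(a$images, b$images)

  # growing n_images never reshuffles earlier images
  big <- generate_ground_truth(synthetic_config(n_images = 8, seed = 11))
  small_ids <- a$images$image_id
  expect_identical(
    big$images[big$images$image_id %in% small_ids, ],
    a$images
  )
  keep <- Filter(function(x) x$image_id <= 5, big$annotations)
  expect_identical(
    lapply(keep, function(x) unclass(x)[c("image_id", "bbox", "area", "keypoints")]),
    lapply(a$annotations, function(x) unclass(x)[c("image_id", "bbox", "area", "keypoints")])
  )

  # and the generator never disturbs the caller's RNG stream
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generate_ground_truth(config))
  expect_identical(runif(3), before)
})

test_that("generated keypoints encode the sampled bone-loss percentage exactly", {
  config <- synthetic_config(n_images = 15, seed = 21)
  truth <- generate_ground_truth(config)
  loss <- attr(truth, "loss_percent")
  for (ann in truth$annotations) {
    m <- measure_bone_loss(ann$keypoints)
    expect_equal(m$percentage, loss[[as.character(ann$annotation_id)]],
      tolerance = 1e-6
    )
    expect_equal(implant_scale(ann), sqrt(ann$area))
  }
})

test_that("degenerate loss distributions force the advertised geometry", {
  zero <- synthetic_config(
    n_images = 6, seed = 3,
    loss_weights = c(1, 0, 0, 0),
    loss_bins = list(c(0, 0), c(10, 25), c(25, 50), c(50, 85))
  )
  truth <- generate_ground_truth(zero)
  for (ann in truth$annotations) {
    m <- measure_bone_loss(ann$keypoints)
    expect_equal(m$defect_length, 0, tolerance = 1e-9)
    expect_equal(
      unname(m$midpoints$bone_level), unname(m$midpoints$top),
      tolerance = 1e-9
    )
  }

  severe <- synthetic_config(
    n_images = 40, implants_per_image = c(2L, 3L), seed = 4,
    loss_weights = c(0, 0, 0, 1),
    loss_bins = list(c(0, 10), c(10, 25), c(25, 50), c(50, 100))
  )
  truth_s <- generate_ground_truth(severe)
  expect_gte(length(truth_s$annotations), 80)
  sev <- vapply(truth_s$annotations, function(a) {
    measure_bone_loss(a$keypoints)$severity
  }, character(1))
  expect_true(all(sev == "severe"))
})

test_that("zero-noise perturbation reproduces the truth and a perfect mean OKS", {
  config <- synthetic_config(
    n_images = 5, sigma_true = rep(0, 6), fp_rate = 0, fn_rate = 0,
    box_jitter_px = 0, seed = 6
  )
  truth <- generate_ground_truth(config)
  preds <- perturb_to_predictions(truth, config)
  expect_length(preds, length(truth$annotations))
  for (i in seq_along(preds)) {
    expect_equal(
      unclass(preds[[i]]$keypoints)[, c("x", "y")],
      unclass(truth$annotations[[i]]$keypoints)[, c("x", "y")]
    )
  }
  expect_equal(mean_oks(truth, preds)$mean_oks, 1)
})

test_that("the miss rate shows up as recall at all detections", {
  config <- synthetic_config(
    n_images = 400, implants_per_image = c(2L, 3L),
    fn_rate = 0.2, fp_rate = 0, seed = 31
  )
  truth <- generate_ground_truth(config)
  preds <- perturb_to_predictions(truth, config)
  recall <- length(preds) / length(truth$annotations)
  expect_equal(recall, 0.8, tolerance = 0.04)
})

test_that("redundant annotations support sigma recovery and its ordering", {
  config <- synthetic_config(
    n_images = 500, implants_per_image = c(2L, 2L), seed = 41
  )
  truth <- generate_ground_truth(config)
  ra <- redundant_annotations(truth, config)
  expect_length(ra$second, length(truth$annotations))
  fit <- calibrate_sigma(truth$annotations, ra$second, ra$pairing)
  rel_err <- abs(fit$sigma / config$sigma_true - 1)
  expect_true(all(rel_err < 0.10))
  # bone-level sigmas exceed apex/top sigmas in the recovered vector too
  expect_gt(min(fit$sigma[1:2]), max(fit$sigma[3:6]))

  zero <- synthetic_config(n_images = 3, sigma_true = rep(0, 6), seed = 42)
  truth0 <- generate_ground_truth(zero)
  ra0 <- redundant_annotations(truth0, zero)
  fit0 <- calibrate_sigma(truth0$annotations, ra0$second, ra0$pairing)
  expect_equal(unname(fit0$sigma), rep(0, 6))
})

test_that("correlated score mode ranks better keypoints higher", {
  config <- synthetic_config(
    n_images = 60, sigma_true = default_sigma() * 3, fp_rate = 0,
    fn_rate = 0, score_mode = "correlated", seed = 51
  )
  truth <- generate_ground_truth(config)
  preds <- perturb_to_predictions(truth, config)
  report <- mean_oks(truth, preds, detection_threshold = 0)
  scores <- vapply(preds, function(p) mean(p$keypoint_scores), numeric(1))
  oks_by_pred <- vapply(seq_along(preds), function(i) {
    oks(truth$annotations[[i]], preds[[i]]$keypoints)
  }, numeric(1))
  expect_gt(cor(scores, oks_by_pred, method = "spearman"), 0.5)
  expect_lt(report$mean_oks, 1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(fp_rate = 1.5))
  expect_error(synthetic_config(loss_weights = c(0.5, 0.5, 0.2, 0.1)))
  expect_error(
    generate_ground_truth(synthetic_config(
      image_size = c(100, 100), length_px = c(300, 300)
    )),
    "does not fit"
  )
})
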