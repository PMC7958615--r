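test_that("iou reproduces rectangle-area arithmetic", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  # overlap 1, union 4 + 4 - 1 = 7
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_equal(
    iou(c(0, 0, 2, 2), c(1, 1, 2, 2)),
    iou(c(1, 1, 2, 2), c(0, 0, 2, 2))
  )
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "positive")
})

test_that("implant scale is the square root of the segmented area", {
  expect_equal(implant_scale(make_ann(len = 10, wid = 10)), 10)
  ann <- make_ann()
  ann$area <- 2
  expect_equal(implant_scale(ann), sqrt(2))
  ann$area <- 0
  expect_error(implant_scale(ann), "positive")
})

test_that("oks matches the closed form of the keypoint similarity", {
  ann <- make_ann() # s^2 = 4000
  expect_equal(oks(ann, ann$keypoints), 1)

  # one labeled keypoint displaced by d = 2 * sigma_i * s -> exp(-1/2)
  sigma <- default_sigma()
  s <- implant_scale(ann)
  one_v <- make_ann(v = c(2L, rep(0L, 5L)))
  kp <- one_v$keypoints
  kp[1, "x"] <- kp[1, "x"] + 2 * sigma[1] * s
  expect_equal(oks(one_v, kp, sigma), exp(-0.5))

  # all six displaced by d = 0.9725 * sigma_i * s -> 0.8885 (4 dp)
  kp6 <- ann$keypoints
  kp6[, "x"] <- kp6[, "x"] + 0.9725 * sigma * s
  expect_equal(round(oks(ann, kp6, sigma), 4), 0.8885)

  # unlabeled ground-truth keypoints are ignored wherever they landed
  kp[2, "x"] <- kp[2, "x"] + 1e6
  expect_equal(oks(one_v, kp, sigma), exp(-0.5))

  expect_error(oks(make_ann(v = rep(0L, 6L)), ann$keypoints), "v = 0")
  expect_error(oks(ann, ann$keypoints, sigma = rep(0, 6)), "sigma")
})

test_that("oks is invariant to joint translation and uniform scaling", {
  set.seed(42)
  for (i in 1:50) {
    ann <- make_ann(
      origin = runif(2, 50, 400), len = runif(1, 100, 300),
      wid = runif(1, 20, 80), f = runif(1)
    )
    kp <- ann$keypoints
    kp[, "x"] <- kp[, "x"] + rnorm(6, 0, 5)
    kp[, "y"] <- kp[, "y"] + rnorm(6, 0, 5)
    base <- oks(ann, kp)

    shift <- runif(2, -100, 100)
    ann_t <- ann
    ann_t$keypoints[, c("x", "y")] <- ann_t$keypoints[, c("x", "y")] +
      rep(shift, each = 6)
    kp_t <- kp
    kp_t[, c("x", "y")] <- kp_t[, c("x", "y")] + rep(shift, each = 6)
    expect_equal(oks(ann_t, kp_t), base)

    c_scale <- runif(1, 0.3, 3)
    ann_s <- ann
    ann_s$keypoints[, c("x", "y")] <- ann_s$keypoints[, c("x", "y")] * c_scale
    ann_s$area <- ann_s$area * c_scale^2
    kp_s <- kp
    kp_s[, c("x", "y")] <- kp_s[, c("x", "y")] * c_scale
    expect_equal(oks(ann_s, kp_s), base)
  }
})

test_that("oks strictly decreases as any labeled displacement grows", {
  set.seed(7)
  ann <- make_ann()
  s <- implant_scale(ann)
  for (i in 1:6) {
    kp <- ann$keypoints
    prev <- oks(ann, kp)
    for (d in c(0.5, 1, 2, 5) * s * default_sigma()[i]) {
      kp[i, "y"] <- ann$keypoints[i, "y"] + d
      now <- oks(ann, kp)
      expect_lt(now, prev)
      prev <- now
    }
  }
})

test_that("calibrate_sigma reproduces the mean-of-squares formula by hand", {
  # identical sets -> sigma exactly 0
  anns <- list(make_ann(id = 1L), make_ann(id = 2L, origin = c(400, 100)))
  pairing <- stats::setNames(c(1, 2), c(1, 2))
  fit <- calibrate_sigma(anns, anns, pairing)
  expect_equal(unname(fit$sigma), rep(0, 6))
  expect_equal(unname(fit$n), rep(2L, 6L))

  # two implants with d^2/s^2 of 0.01 and 0.03 for keypoint 1 -> sqrt(0.02)
  s <- implant_scale(anns[[1]])
  second <- lapply(anns, function(a) a)
  second[[1]]$keypoints[1, "x"] <- second[[1]]$keypoints[1, "x"] + sqrt(0.01) * s
  second[[2]]$keypoints[1, "x"] <- second[[2]]$keypoints[1, "x"] + sqrt(0.03) * s
  fit <- calibrate_sigma(anns, second, pairing)
  expect_equal(unname(fit$sigma[1]), sqrt(0.02))
  expect_equal(unname(fit$sigma[2:6]), rep(0, 5))

  expect_error(calibrate_sigma(anns, anns, stats::setNames(numeric(0), character(0))), "empty")

  # a keypoint type labeled in neither pass is an error naming the type
  unlab <- lapply(anns, function(a) {
    a$keypoints[3, "v"] <- 0
    a
  })
  expect_error(calibrate_sigma(unlab, unlab, pairing), "lt_apex")
})

test_that("calibrate_sigma recovers a known sigma from simulated redundancy", {
  config <- synthetic_config(
    n_images = 250, implants_per_image = c(2L, 2L), seed = 101
  )
  truth <- generate_ground_truth(config) # 500 implants
  ra <- redundant_annotations(truth, config)
  fit <- calibrate_sigma(truth$annotations, ra$second, ra$pairing)
  rel_err <- abs(fit$sigma / config$sigma_true - 1)
  expect_true(all(rel_err < 0.10))
})

test_that("single-keypoint inversion closes the loop with the multiplier", {
  set.seed(3)
  for (m in c(0.1, 0.5, 0.9725, 2, 3)) {
    ann <- make_ann()
    s <- implant_scale(ann)
    kp <- ann$keypoints
    theta <- runif(6, 0, 2 * pi)
    kp[, "x"] <- kp[, "x"] + m * default_sigma() * s * cos(theta)
    kp[, "y"] <- kp[, "y"] + m * default_sigma() * s * sin(theta)
    expect_equal(oks_to_sigma_multiplier(oks(ann, kp)), m, tolerance = 1e-8)
  }
})
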