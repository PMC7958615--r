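# Synthetic radiograph annotations with the statistical structure the
# metrics assume: implants as rotated rectangles whose corners define the
# six landmarks, bone levels placed at a sampled loss percentage along the
# implant axis, and predictions displaced by isotropic Gaussian noise whose
# per-axis SD s * sigma_i / sqrt(2) makes E[d^2 / s^2] = sigma_i^2 exact.
# No pixel texture is imitated; only geometry and scores.

#' Configuration for the synthetic generator
#'
#' Defaults describe a small but realistic periapical study: 1000 x 800 px
#' radiographs, 1-3 implants each, implant lengths 150-300 px, tilts within
#' 15 degrees of vertical, a bone-loss mixture dominated by normal/early
#' cases, true annotation noise at the shipped sigma calibration, and a
#' detector with 5% miss and 5% false-positive rates.
#'
#' @param n_images Number of images.
#' @param implants_per_image Integer range `c(min, max)`.
#' @param jaw_mix Proportion of upper-jaw images.
#' @param image_size `c(width, height)` in pixels.
#' @param length_px,width_px Implant body length/width ranges in pixels.
#' @param tilt_deg Tilt range (degrees from vertical).
#' @param loss_weights Mixture weights over the four severity bins (sum 1).
#' @param loss_bins List of four `c(lo, hi)` percentage intervals sampled
#'   uniformly within the chosen bin.
#' @param sigma_true Per-keypoint noise scale for predictions and redundant
#'   annotations; default [default_sigma()].
#' @param tp_score_range,fp_score_range Score ranges for true detections and
#'   injected false positives.
#' @param fp_rate,fn_rate False-positive injection and miss probabilities.
#' @param box_jitter_px SD of the box-coordinate jitter on predictions.
#' @param score_mode `"independent"` (scores uniform in range) or
#'   `"correlated"` (scores decrease with keypoint displacement, making PR
#'   curves informative).
#' @param seed Base seed; every image gets its own random stream keyed by
#'   `(seed, image index)`, so growing `n_images` never reshuffles earlier
#'   images.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 20L,
                             implants_per_image = c(1L, 3L),
                             jaw_mix = 0.5,
                             image_size = c(1000L, 800L),
                             length_px = c(150, 300),
                             width_px = c(45, 80),
                             tilt_deg = c(-15, 15),
                             loss_weights = c(0.4, 0.25, 0.2, 0.15),
                             loss_bins = list(
                               c(0, 10), c(10, 25),
                               c(25, 50), c(50, 85)
                             ),
                             sigma_true = default_sigma(),
                             tp_score_range = c(0.75, 0.99),
                             fp_score_range = c(0.05, 0.5),
                             fp_rate = 0.05,
                             fn_rate = 0.05,
                             box_jitter_px = 2,
                             score_mode = c("independent", "correlated"),
                             seed = 1L) {
  score_mode <- match.arg(score_mode)
  stopifnot(
    n_images >= 1L,
    length(implants_per_image) == 2L,
    implants_per_image[1L] >= 1L,
    implants_per_image[2L] >= implants_per_image[1L],
    jaw_mix >= 0, jaw_mix <= 1,
    fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1,
    length(loss_weights) == length(loss_bins),
    abs(sum(loss_weights) - 1) < 1e-9,
    diff(length_px) >= 0, diff(width_px) >= 0
  )
  check_sigma(sigma_true)
  structure(
    list(
      n_images = as.integer(n_images),
      implants_per_image = as.integer(implants_per_image),
      jaw_mix = jaw_mix,
      image_size = as.numeric(image_size),
      length_px = length_px, width_px = width_px, tilt_deg = tilt_deg,
      loss_weights = loss_weights, loss_bins = loss_bins,
      sigma_true = as.numeric(sigma_true),
      tp_score_range = tp_score_range, fp_score_range = fp_score_range,
      fp_rate = fp_rate, fn_rate = fn_rate,
      box_jitter_px = box_jitter_px,
      score_mode = score_mode,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# one stream per (seed, image, operation); evaluated with the global RNG
# state saved and restored, so the generator never perturbs a caller's RNG
stream_seed <- function(seed, image_index, op) {
  (((seed %% 65011L) * 33013) + image_index * 7919 + op * 104729) %% 2147483629
}

with_stream <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

sample_loss_percent <- function(config) {
  bin <- sample.int(length(config$loss_weights), 1L, prob = config$loss_weights)
  stats::runif(1L, config$loss_bins[[bin]][1L], config$loss_bins[[bin]][2L])
}

# rotated-rectangle implant: axis unit u points from top (coronal) to apex
# (apical, increasing y); keypoints are the rectangle corners plus the two
# bone-level points at fraction f of the length down each side.
implant_geometry <- function(center, len, wid, tilt_deg, loss_percent) {
  t <- tilt_deg * pi / 180
  u <- c(sin(t), cos(t))
  p <- c(cos(t), -sin(t))
  top_a <- center - u * len / 2 + p * wid / 2
  top_b <- center - u * len / 2 - p * wid / 2
  # "left" is the side whose top corner has the smaller x; the same side
  # assignment is reused for apex and bone level so sides stay consistent
  if (top_a[1L] <= top_b[1L]) {
    lt_top <- top_a
    rt_top <- top_b
    lt_sign <- 1
  } else {
    lt_top <- top_b
    rt_top <- top_a
    lt_sign <- -1
  }
  lt_apex <- center + u * len / 2 + lt_sign * p * wid / 2
  rt_apex <- center + u * len / 2 - lt_sign * p * wid / 2
  f <- loss_percent / 100
  lt_bone <- lt_top + u * (f * len)
  rt_bone <- rt_top + u * (f * len)
  pts <- rbind(lt_bone, rt_bone, lt_apex, rt_apex, lt_top, rt_top)
  corners <- rbind(lt_top, rt_top, lt_apex, rt_apex)
  bbox <- c(
    min(corners[, 1L]), min(corners[, 2L]),
    diff(range(corners[, 1L])), diff(range(corners[, 2L]))
  )
  list(
    keypoints = keypoints(pts[, 1L], pts[, 2L]),
    bbox = bbox,
    area = len * wid
  )
}

#' Generate a synthetic ground-truth bundle
#'
#' Implants are placed as rotated rectangles fully inside the image; the six
#' keypoints derive exactly from the rectangle (apex corners, most-coronal
#' corners as implant top, bone-level points at the sampled loss percentage
#' down each side), so [measure_bone_loss()] on the generated keypoints
#' recovers the sampled percentage up to rounding. Area is the rectangle
#' area, the bbox its axis-aligned envelope, all visibilities 2.
#'
#' @param config A [synthetic_config()].
#' @return A [dataset_bundle()]; attribute `"loss_percent"` carries the
#'   per-annotation sampled percentages (named by annotation id) and
#'   attribute `"config"` the generating configuration.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$image_size[1L]
  h <- config$image_size[2L]
  margin <- 5
  images <- data.frame(
    image_id = seq_len(config$n_images), width = w, height = h,
    jaw = NA_character_
  )
  annotations <- list()
  loss_percent <- numeric(0)
  next_id <- 1L
  for (i in seq_len(config$n_images)) {
    made <- with_stream(stream_seed(config$seed, i, 0L), {
      jaw <- if (stats::runif(1L) < config$jaw_mix) "upper" else "lower"
      lo_n <- config$implants_per_image[1L]
      hi_n <- config$implants_per_image[2L]
      n_impl <- lo_n + sample.int(hi_n - lo_n + 1L, 1L) - 1L
      impls <- lapply(seq_len(n_impl), function(k) {
        len <- stats::runif(1L, config$length_px[1L], config$length_px[2L])
        wid <- stats::runif(1L, config$width_px[1L], config$width_px[2L])
        tilt <- stats::runif(1L, config$tilt_deg[1L], config$tilt_deg[2L])
        f <- sample_loss_percent(config)
        t <- tilt * pi / 180
        hx <- abs(sin(t)) * len / 2 + abs(cos(t)) * wid / 2
        hy <- abs(cos(t)) * len / 2 + abs(sin(t)) * wid / 2
        if (2 * (hx + margin) >= w || 2 * (hy + margin) >= h) {
          stop("implant geometry does not fit the image (length ", round(len),
            " px in ", w, " x ", h, ")",
            call. = FALSE
          )
        }
        center <- c(
          stats::runif(1L, hx + margin, w - hx - margin),
          stats::runif(1L, hy + margin, h - hy - margin)
        )
        c(implant_geometry(center, len, wid, tilt, f), list(loss = f))
      })
      list(jaw = jaw, impls = impls)
    })
    images$jaw[i] <- made$jaw
    for (impl in made$impls) {
      annotations[[next_id]] <- implant_annotation(
        annotation_id = next_id, image_id = i,
        bbox = impl$bbox, area = impl$area, keypoints = impl$keypoints
      )
      loss_percent[as.character(next_id)] <- impl$loss
      next_id <- next_id + 1L
    }
  }
  bundle <- dataset_bundle(images = images, annotations = annotations)
  attr(bundle, "loss_percent") <- loss_percent
  attr(bundle, "config") <- config
  bundle
}

perturbed_keypoints <- function(kp, s, sigma_true) {
  m <- unclass(kp)
  sd_axis <- s * sigma_true / sqrt(2)
  dx <- stats::rnorm(6L, 0, sd_axis)
  dy <- stats::rnorm(6L, 0, sd_axis)
  keypoints(m[, "x"] + dx, m[, "y"] + dy, m[, "v"])
}

score_in <- function(range, n = 1L) stats::runif(n, range[1L], range[2L])

#' Perturb a ground-truth bundle into detector-like predictions
#'
#' Each implant is dropped with probability `fn_rate` (a miss); the kept
#' implants get keypoints displaced by isotropic Gaussian noise with per-axis
#' SD `s * sigma_true_i / sqrt(2)` — so the expected squared normalized
#' displacement equals `sigma_true_i^2` exactly — a jittered box, and scores
#' from the true-positive range. False positives with random geometry and
#' low-range scores are injected at rate `fp_rate` per true implant. In
#' `"correlated"` score mode, scores decrease with the implant's actual
#' keypoint displacement instead of being drawn independently.
#'
#' @param truth A [dataset_bundle()] (typically from
#'   [generate_ground_truth()]).
#' @param config A [synthetic_config()].
#' @return List of [implant_prediction()] objects.
#' @export
perturb_to_predictions <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  preds <- list()
  for (i in seq_len(nrow(truth$images))) {
    img <- truth$images[i, ]
    anns <- Filter(function(a) a$image_id == img$image_id, truth$annotations)
    made <- with_stream(stream_seed(config$seed, i, 1L), {
      out <- list()
      for (a in anns) {
        if (stats::runif(1L) < config$fn_rate) next
        s <- implant_scale(a)
        kp <- perturbed_keypoints(a$keypoints, s, config$sigma_true)
        jit <- stats::rnorm(4L, 0, config$box_jitter_px)
        bbox <- c(
          a$bbox[1L] + jit[1L], a$bbox[2L] + jit[2L],
          max(1, a$bbox[3L] + jit[3L]), max(1, a$bbox[4L] + jit[4L])
        )
        if (config$score_mode == "correlated") {
          d_norm <- sqrt(
            (kp[, "x"] - a$keypoints[, "x"])^2 +
              (kp[, "y"] - a$keypoints[, "y"])^2
          ) / (s * pmax(config$sigma_true, 1e-12))
          sim <- exp(-d_norm^2 / 8)
          lo <- config$tp_score_range[1L]
          hi <- config$tp_score_range[2L]
          box_score <- lo + (hi - lo) * mean(sim)
          kp_scores <- lo + (hi - lo) * sim
        } else {
          box_score <- score_in(config$tp_score_range)
          kp_scores <- score_in(config$tp_score_range, 6L)
        }
        out[[length(out) + 1L]] <- implant_prediction(
          image_id = a$image_id, bbox = bbox, box_score = box_score,
          keypoints = kp, keypoint_scores = kp_scores
        )
      }
      n_fp <- stats::rbinom(1L, length(anns), config$fp_rate)
      for (k in seq_len(n_fp)) {
        len <- stats::runif(1L, config$length_px[1L], config$length_px[2L])
        wid <- stats::runif(1L, config$width_px[1L], config$width_px[2L])
        x <- stats::runif(1L, 0, img$width - wid)
        y <- stats::runif(1L, 0, img$height - len)
        xs <- stats::runif(6L, x, x + wid)
        ys <- stats::runif(6L, y, y + len)
        out[[length(out) + 1L]] <- implant_prediction(
          image_id = img$image_id,
          bbox = c(x, y, wid, len),
          box_score = score_in(config$fp_score_range),
          keypoints = keypoints(xs, ys),
          keypoint_scores = score_in(config$fp_score_range, 6L)
        )
      }
      out
    })
    preds <- c(preds, made)
  }
  preds
}

#' Re-annotate a bundle to emulate a second expert pass
#'
#' Every implant is re-annotated with keypoint displacement noise at
#' `sigma_true` (no misses, no false positives), yielding the paired sets a
#' sigma calibration needs, together with the identity pairing.
#'
#' @inheritParams perturb_to_predictions
#' @return List with `second` (list of [implant_annotation()]) and `pairing`
#'   (named vector: first-set annotation id to second-set annotation id).
#' @export
redundant_annotations <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  id_offset <- 1000000L
  second <- list()
  pairing <- numeric(0)
  for (i in seq_len(nrow(truth$images))) {
    anns <- Filter(
      function(a) a$image_id == truth$images$image_id[i],
      truth$annotations
    )
    made <- with_stream(stream_seed(config$seed, i, 2L), {
      lapply(anns, function(a) {
        implant_annotation(
          annotation_id = a$annotation_id + id_offset,
          image_id = a$image_id, bbox = a$bbox, area = a$area,
          keypoints = perturbed_keypoints(
            a$keypoints, implant_scale(a), config$sigma_true
          )
        )
      })
    })
    second <- c(second, made)
    for (a in anns) {
      pairing[as.character(a$annotation_id)] <- a$annotation_id + id_offset
    }
  }
  list(second = second, pairing = pairing)
}

#' One-call synthetic study
#'
#' Convenience wrapper producing the ground truth, detector-like predictions
#' and provenance in one object.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_bundle` with `truth`, `predictions`,
#'   `config` and `loss_percent`.
#' @export
synthetic_bundle <- function(config = synthetic_config()) {
  truth <- generate_ground_truth(config)
  structure(
    list(
      truth = truth,
      predictions = perturb_to_predictions(truth, config),
      config = config,
      loss_percent = attr(truth, "loss_percent")
    ),
    class = "synthetic_bundle"
  )
}
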