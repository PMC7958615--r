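#' Default per-keypoint tolerance vector
#'
#' Normalized standard deviations sigma_i of repeated expert annotation, one
#' per keypoint type in schema order (left/right bone level, left/right apex,
#' left/right implant top), unitless after division by the implant scale
#' `s = sqrt(area)`. These are the shipped calibration obtained from a test
#' set annotated twice; the bone-level entries are markedly larger than the
#' apex/top entries because the marginal bone level is the hardest landmark
#' to place, even for a dentist. The OKS tolerance is `k_i = 2 * sigma_i`.
#'
#' @return Named numeric vector of length 6.
#' @export
#' @examples
#' default_sigma()
default_sigma <- function() {
  stats::setNames(
    c(0.0895, 0.0816, 0.0193, 0.0196, 0.0209, 0.0273),
    keypoint_schema()$names
  )
}

check_sigma <- function(sigma) {
  if (length(sigma) != 6L || any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("sigma must be 6 finite non-negative values in schema order",
      call. = FALSE
    )
  }
  invisible(as.numeric(sigma))
}

# xywh -> (x1, y1, x2, y2) half-open
xywh_to_xyxy <- function(b) c(b[1L], b[2L], b[1L] + b[3L], b[2L] + b[4L])

#' Intersection over union of two boxes
#'
#' Overlap area of the two rectangles divided by the area of their union
#' (Jaccard index). Boxes are `(x, y, width, height)` in pixels.
#'
#' @param box_a,box_b Numeric length-4 boxes; width and height must be
#'   positive.
#' @return A value in `[0, 1]`, symmetric in its arguments.
#' @export
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 2, 2)) # 1/7
iou <- function(box_a, box_b) {
  if (length(box_a) != 4L || length(box_b) != 4L ||
    box_a[3L] <= 0 || box_a[4L] <= 0 || box_b[3L] <= 0 || box_b[4L] <= 0) {
    stop("iou requires two (x, y, w, h) boxes with positive width and height",
      call. = FALSE
    )
  }
  a <- xywh_to_xyxy(box_a)
  b <- xywh_to_xyxy(box_b)
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  union <- box_a[3L] * box_a[4L] + box_b[3L] * box_b[4L] - inter
  inter / union
}

#' Implant scale
#'
#' The OKS normalizer `s`: the square root of the ground-truth segmented
#' implant area. There is no silent fall-back to the bounding box; a missing
#' or non-positive area is an error.
#'
#' @param ann An [implant_annotation()].
#' @return Positive scale in pixels.
#' @export
implant_scale <- function(ann) {
  if (is.null(ann$area) || !is.finite(ann$area) || ann$area <= 0) {
    stop("implant scale requires a positive segmented area", call. = FALSE)
  }
  sqrt(ann$area)
}

#' Object keypoint similarity for one implant
#'
#' For implant `j` with ground-truth keypoints and a set of predicted
#' keypoints, OKS is the mean over labeled keypoints (`v > 0`) of
#' `exp(-d_i^2 / (2 s^2 k_i^2))`, where `d_i` is the Euclidean pixel
#' displacement of keypoint `i`, `s = sqrt(area)` is the implant scale and
#' `k_i = k_constant * sigma_i` (the field's convention sets the constant
#' to 2). It equals 1 exactly when every labeled keypoint coincides with its
#' ground truth and decreases strictly as any labeled displacement grows.
#' Keypoints with `v = 1` (labeled but not visible) count; an implant with
#' no labeled keypoint has no defined OKS and is an error here — callers
#' exclude such implants rather than score them 0.
#'
#' @param gt An [implant_annotation()] providing keypoints, visibility and
#'   scale.
#' @param predicted_keypoints A `keypoint_matrix` of the 6 predicted points.
#' @param sigma Per-keypoint tolerance vector; default [default_sigma()].
#'   All entries must be strictly positive.
#' @param k_constant Multiplier turning sigma into the OKS tolerance
#'   `k_i`; default 2.
#' @return OKS in `[0, 1]`.
#' @export
oks <- function(gt, predicted_keypoints, sigma = default_sigma(),
                k_constant = 2) {
  sigma <- check_sigma(sigma)
  if (any(sigma == 0)) {
    stop("oks is degenerate for zero sigma entries", call. = FALSE)
  }
  g <- unclass(gt$keypoints)
  p <- unclass(predicted_keypoints)
  labeled <- g[, "v"] > 0
  if (!any(labeled)) {
    stop("OKS undefined: no ground-truth keypoint is labeled (all v = 0)",
      call. = FALSE
    )
  }
  s2 <- gt$area
  k <- k_constant * sigma
  d2 <- (g[, "x"] - p[, "x"])^2 + (g[, "y"] - p[, "y"])^2
  sims <- exp(-d2 / (2 * s2 * k^2))
  mean(sims[labeled])
}

#' Normalized keypoint displacements between two annotation sets
#'
#' For each implant pair the per-keypoint displacement `d` divided by the
#' implant scale `s` of the first (reference) set, with a mask of keypoints
#' labeled (`v > 0`) in both sets. This is the raw material of the sigma
#' calibration.
#'
#' @param first,second Lists of [implant_annotation()] objects.
#' @param pairing Named vector or list mapping annotation ids in `first` to
#'   annotation ids in `second`.
#' @return A list with `d_over_s` (n-pairs x 6 matrix) and `labeled`
#'   (logical mask of the same shape).
#' @export
normalized_displacements <- function(first, second, pairing) {
  if (length(pairing) == 0L) {
    stop("empty pairing: nothing to compare", call. = FALSE)
  }
  id_of <- function(set) vapply(set, function(a) as.numeric(a$annotation_id), numeric(1))
  first_ids <- id_of(first)
  second_ids <- id_of(second)
  a_ids <- as.numeric(names(pairing))
  b_ids <- as.numeric(unlist(pairing))
  n <- length(a_ids)
  d_over_s <- matrix(NA_real_, n, 6L)
  labeled <- matrix(FALSE, n, 6L)
  colnames(d_over_s) <- colnames(labeled) <- keypoint_schema()$names
  for (i in seq_len(n)) {
    ia <- match(a_ids[i], first_ids)
    ib <- match(b_ids[i], second_ids)
    if (is.na(ia) || is.na(ib)) {
      stop("pairing references annotation ids absent from the sets (",
        a_ids[i], " -> ", b_ids[i], ")",
        call. = FALSE
      )
    }
    a <- first[[ia]]
    b <- second[[ib]]
    s <- implant_scale(a)
    ka <- unclass(a$keypoints)
    kb <- unclass(b$keypoints)
    m <- ka[, "v"] > 0 & kb[, "v"] > 0
    d <- sqrt((ka[, "x"] - kb[, "x"])^2 + (ka[, "y"] - kb[, "y"])^2)
    d_over_s[i, ] <- d / s
    labeled[i, ] <- m
  }
  list(d_over_s = d_over_s, labeled = labeled)
}

#' Calibrate per-keypoint sigma from redundant annotations
#'
#' Given two independent annotation passes over the same implants,
#' `sigma_i^2` is estimated as the mean over paired implants `j` of
#' `d_ji^2 / s_j^2` — the squared keypoint displacement normalized by the
#' implant scale of the first (reference) set. Only implants where keypoint
#' `i` is labeled in both passes contribute; a keypoint type with no usable
#' pair is an error naming the type.
#'
#' @inheritParams normalized_displacements
#' @return Object of class `sigma_calibration`: list with `sigma` (length-6
#'   named vector) and `n` (per-keypoint effective pair counts).
#' @export
calibrate_sigma <- function(first, second, pairing) {
  nd <- normalized_displacements(first, second, pairing)
  ratio2 <- nd$d_over_s^2
  ratio2[!nd$labeled] <- NA_real_
  n_eff <- colSums(nd$labeled)
  if (any(n_eff == 0L)) {
    bad <- keypoint_schema()$names[n_eff == 0L]
    stop("no usable annotation pairs for keypoint type(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  sigma <- sqrt(colMeans(ratio2, na.rm = TRUE))
  structure(
    list(sigma = sigma, n = n_eff),
    class = "sigma_calibration"
  )
}

#' @export
print.sigma_calibration <- function(x, ...) {
  cat("<sigma_calibration> per-keypoint normalized annotation SD\n")
  print(round(x$sigma, 4))
  cat("effective pairs per keypoint:\n")
  print(x$n)
  invisible(x)
}
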