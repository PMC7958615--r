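# Converts one implant's six landmarks into a radiographic bone-loss
# percentage and a four-level peri-implantitis severity class. The sound-bone
# reference is the most coronal implant thread ("implant top"); total length
# runs from the apex midpoint to the top midpoint, the defect from the top
# midpoint to the marginal bone-level midpoint.

#' Severity scale for radiographic bone loss
#'
#' Four classes over the bone-loss percentage with half-open bins closed on
#' the left class: normal (<= first threshold), then one class per interval
#' up to 100. Defaults: normal <= 10, early (10, 25], moderate (25, 50],
#' severe > 50.
#'
#' @param thresholds Three strictly increasing percentages in `(0, 100)`.
#' @param labels Four class names, one more than thresholds.
#' @return Object of class `severity_scale`.
#' @export
severity_scale <- function(thresholds = c(10, 25, 50),
                           labels = c("normal", "early", "moderate", "severe")) {
  if (length(thresholds) + 1L != length(labels)) {
    stop("need exactly one more label than threshold", call. = FALSE)
  }
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) ||
    any(thresholds >= 100)) {
    stop("thresholds must be strictly increasing within (0, 100)",
      call. = FALSE
    )
  }
  structure(
    list(thresholds = as.numeric(thresholds), labels = as.character(labels)),
    class = "severity_scale"
  )
}

#' Classify a bone-loss percentage
#'
#' Bin boundaries belong to the class on their left: with the default scale,
#' 10% is still normal, 25% still early, 50% still moderate; anything above
#' 50% is severe.
#'
#' @param percentage Bone-loss percentage in `[0, 100]` (vectorized).
#' @param scale A [severity_scale()].
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_severity(c(10, 10.5, 50, 50.5))
classify_severity <- function(percentage, scale = severity_scale()) {
  if (any(!is.finite(percentage)) || any(percentage < 0) ||
    any(percentage > 100)) {
    stop("percentage must lie in [0, 100]", call. = FALSE)
  }
  idx <- findInterval(percentage, scale$thresholds,
    left.open = TRUE, rightmost.closed = FALSE
  ) + 1L
  scale$labels[idx]
}

#' Midpoint of a left/right keypoint pair
#'
#' @param left,right Numeric `(x, y, v)` rows of a keypoint matrix (or any
#'   length-2+ numeric with named or positional x, y); both must be labeled
#'   (`v > 0`) when a `v` entry is present.
#' @return Numeric `(x, y)` midpoint.
#' @export
keypoint_midpoint <- function(left, right) {
  check_side <- function(kp, side) {
    if (length(kp) >= 3L && kp[3L] <= 0) {
      stop("cannot take midpoint: ", side, " keypoint is not labeled (v = 0)",
        call. = FALSE
      )
    }
  }
  check_side(left, "left")
  check_side(right, "right")
  c(
    x = (as.numeric(left[1L]) + as.numeric(right[1L])) / 2,
    y = (as.numeric(left[2L]) + as.numeric(right[2L])) / 2
  )
}

#' Measure radiographic bone loss from six keypoints
#'
#' Total implant length is the Euclidean distance from the apex midpoint to
#' the implant-top midpoint; the defect length is the distance from the top
#' midpoint to the marginal bone-level midpoint. The bone-level midpoint is
#' projected onto the apex-top axis to determine its side: at or coronal to
#' the top the defect is clamped to 0 (bone gain must not read as loss).
#' A bone level apical to the apex midpoint would exceed 100%; the
#' percentage is then clamped to 100 and flagged, since such radiographs do
#' occur. Severity is attached via [classify_severity()].
#'
#' @param kp A `keypoint_matrix` with all six keypoints labeled (`v > 0`).
#' @param scale A [severity_scale()].
#' @return Object of class `bone_loss_measurement`: list with
#'   `total_length`, `defect_length` (pixels), `percentage`, `severity`,
#'   `midpoints` (list `apex`, `top`, `bone_level`) and `clamped` flag.
#' @export
measure_bone_loss <- function(kp, scale = severity_scale()) {
  if (!is.matrix(kp) || nrow(kp) != 6L) {
    stop("measure_bone_loss needs a 6 x 3 keypoint matrix", call. = FALSE)
  }
  unlabeled <- which(kp[, "v"] <= 0)
  if (length(unlabeled) > 0L) {
    stop("cannot measure bone loss: unlabeled keypoint(s) ",
      paste(keypoint_schema()$names[unlabeled], collapse = ", "),
      call. = FALSE
    )
  }
  bone_mid <- keypoint_midpoint(kp[1L, ], kp[2L, ])
  apex_mid <- keypoint_midpoint(kp[3L, ], kp[4L, ])
  top_mid <- keypoint_midpoint(kp[5L, ], kp[6L, ])
  axis <- apex_mid - top_mid
  total <- sqrt(sum(axis^2))
  if (total == 0) {
    stop("degenerate implant: apex and top midpoints coincide", call. = FALSE)
  }
  proj <- sum((bone_mid - top_mid) * axis) / total
  defect <- if (proj <= 0) 0 else sqrt(sum((bone_mid - top_mid)^2))
  percentage <- 100 * defect / total
  clamped <- percentage > 100
  if (clamped) percentage <- 100
  structure(
    list(
      total_length = total,
      defect_length = defect,
      percentage = percentage,
      severity = classify_severity(percentage, scale),
      midpoints = list(apex = apex_mid, top = top_mid, bone_level = bone_mid),
      clamped = clamped
    ),
    class = "bone_loss_measurement"
  )
}

#' @export
print.bone_loss_measurement <- function(x, ...) {
  cat(sprintf(
    "<bone_loss_measurement> %.1f%% (%s): defect %.1f px of %.1f px total%s\n",
    x$percentage, x$severity, x$defect_length, x$total_length,
    if (x$clamped) " [clamped to 100%]" else ""
  ))
  invisible(x)
}

#' Absolute bone loss from the percentage and the real implant length
#'
#' The radiograph only yields a ratio; multiplying by the implant's known
#' physical length (from its product specification) gives the absolute
#' defect depth, free of radiographic magnification.
#'
#' @param percentage Bone-loss percentage.
#' @param implant_length Real implant length in millimeters, positive.
#' @return Bone loss in millimeters.
#' @export
#' @examples
#' absolute_bone_loss(25, 10) # 2.5 mm
absolute_bone_loss <- function(percentage, implant_length) {
  if (any(!is.finite(implant_length)) || any(implant_length <= 0)) {
    stop("implant_length must be positive", call. = FALSE)
  }
  percentage / 100 * implant_length
}
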