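#' The fixed implant keypoint schema
#'
#' Every implant instance carries six ordered landmarks: the left and right
#' marginal bone levels, the left and right apex corners, and the left and
#' right implant top (most coronal thread). The order is fixed package-wide;
#' it is the order in which the per-keypoint tolerances `sigma` are stated,
#' so files whose category declares a different order are rejected at load
#' rather than silently permuting tolerances.
#'
#' @return A list with `names` (character vector of length 6) and `skeleton`
#'   (list of 3 left-right index pairs).
#' @export
#' @examples
#' keypoint_schema()$names
keypoint_schema <- function() {
  list(
    names = c(
      "lt_bone_level", "rt_bone_level",
      "lt_apex", "rt_apex",
      "lt_implant_top", "rt_implant_top"
    ),
    skeleton = list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  )
}

#' Position of a keypoint label in the schema
#'
#' @param label Keypoint label, e.g. `"lt_apex"`.
#' @return Integer position in 1..6.
#' @export
keypoint_index <- function(label) {
  idx <- match(label, keypoint_schema()$names)
  if (anyNA(idx)) {
    stop("unknown keypoint label: ", paste(label[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  idx
}

#' Build a 6 x 3 keypoint matrix
#'
#' Keypoints are stored as a numeric matrix with one row per keypoint type
#' (schema order) and columns `x`, `y`, `v`. Visibility `v` follows the
#' COCO convention: 0 = not labeled (x, y meaningless), 1 = labeled but not
#' visible, 2 = labeled and visible. Metrics use only `v > 0`.
#'
#' @param x,y Numeric vectors of length 6 (pixel coordinates).
#' @param v Integer visibilities in \{0, 1, 2\}; defaults to 2 for all.
#' @return A 6 x 3 numeric matrix of class `keypoint_matrix`.
#' @export
#' @examples
#' keypoints(x = c(10, 30, 12, 28, 11, 29), y = c(50, 50, 200, 200, 40, 40))
keypoints <- function(x, y, v = rep(2L, 6L)) {
  if (length(x) != 6L || length(y) != 6L || length(v) != 6L) {
    stop("keypoints require exactly 6 x, y and v values", call. = FALSE)
  }
  if (!all(v %in% c(0L, 1L, 2L))) {
    stop("visibility flags must be 0, 1 or 2", call. = FALSE)
  }
  m <- cbind(x = as.numeric(x), y = as.numeric(y), v = as.numeric(v))
  rownames(m) <- keypoint_schema()$names
  class(m) <- c("keypoint_matrix", class(m))
  m
}

#' Convert a flat 18-value COCO keypoint array to a keypoint matrix
#'
#' @param flat Numeric vector `[x1, y1, v1, ..., x6, y6, v6]`.
#' @return A `keypoint_matrix`.
#' @export
keypoints_from_flat <- function(flat) {
  if (length(flat) != 18L) {
    stop("keypoint array must have 18 values (6 x/y/v triples), got ",
      length(flat),
      call. = FALSE
    )
  }
  m <- matrix(as.numeric(flat), ncol = 3L, byrow = TRUE)
  keypoints(m[, 1L], m[, 2L], m[, 3L])
}

#' Flatten a keypoint matrix back to the 18-value COCO array
#'
#' @param kp A `keypoint_matrix`.
#' @return Numeric vector of length 18.
#' @export
keypoints_to_flat <- function(kp) {
  stopifnot(is.matrix(kp), nrow(kp) == 6L)
  as.numeric(t(unclass(kp)[, c("x", "y", "v"), drop = FALSE]))
}

#' One ground-truth implant instance
#'
#' @param annotation_id Unique annotation identifier (integer-like).
#' @param image_id Identifier of the image the implant sits on.
#' @param bbox Numeric length-4 `(x, y, width, height)` in 0-based pixels.
#' @param area Segmented implant area in pixels squared; its square root is
#'   the implant scale `s` used by OKS.
#' @param keypoints A `keypoint_matrix` (see [keypoints()]).
#' @return An object of class `implant_annotation`.
#' @export
implant_annotation <- function(annotation_id, image_id, bbox, area, keypoints) {
  ann <- structure(
    list(
      annotation_id = annotation_id,
      image_id = image_id,
      bbox = as.numeric(bbox),
      area = as.numeric(area),
      keypoints = keypoints
    ),
    class = "implant_annotation"
  )
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (length(ann$bbox) != 4L || ann$bbox[3L] <= 0 || ann$bbox[4L] <= 0) {
    stop("annotation ", ann$annotation_id,
      ": bbox must be (x, y, w, h) with positive width and height",
      call. = FALSE
    )
  }
  if (!is.finite(ann$area) || ann$area <= 0) {
    stop("annotation ", ann$annotation_id, ": area must be positive",
      call. = FALSE
    )
  }
  if (!is.matrix(ann$keypoints) || nrow(ann$keypoints) != 6L) {
    stop("annotation ", ann$annotation_id, ": keypoints must be a 6 x 3 matrix",
      call. = FALSE
    )
  }
  invisible(ann)
}

#' One detected implant instance
#'
#' Detectors emit no visibility information, so prediction keypoints carry
#' `v = 2` uniformly; all metrics consult the ground-truth visibility only.
#'
#' @param image_id Identifier of the image the detection refers to.
#' @param bbox Numeric length-4 `(x, y, width, height)`.
#' @param box_score Detection confidence in `[0, 1]`.
#' @param keypoints A `keypoint_matrix`.
#' @param keypoint_scores Six per-keypoint confidences in `[0, 1]`.
#' @return An object of class `implant_prediction`.
#' @export
implant_prediction <- function(image_id, bbox, box_score, keypoints,
                               keypoint_scores) {
  kp <- keypoints
  kp[, "v"] <- 2
  pred <- structure(
    list(
      image_id = image_id,
      bbox = as.numeric(bbox),
      box_score = as.numeric(box_score),
      keypoints = kp,
      keypoint_scores = as.numeric(keypoint_scores)
    ),
    class = "implant_prediction"
  )
  validate_prediction(pred)
  pred
}

validate_prediction <- function(pred) {
  if (length(pred$bbox) != 4L) {
    stop("prediction bbox must have 4 values", call. = FALSE)
  }
  scores <- c(pred$box_score, pred$keypoint_scores)
  if (length(pred$keypoint_scores) != 6L) {
    stop("predictions require exactly 6 keypoint scores", call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("prediction scores must lie in [0, 1]", call. = FALSE)
  }
  if (!is.matrix(pred$keypoints) || nrow(pred$keypoints) != 6L) {
    stop("prediction keypoints must be a 6 x 3 matrix", call. = FALSE)
  }
  invisible(pred)
}

#' A validated ground-truth dataset
#'
#' @param images Data frame with columns `image_id`, `width`, `height`,
#'   `jaw` (each `"upper"` or `"lower"`). The jaw label is a required image
#'   attribute: stratified reporting needs the label, not a classifier.
#' @param annotations List of [implant_annotation()] objects.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(images, annotations = list()) {
  bundle <- structure(
    list(
      images = as.data.frame(images),
      annotations = annotations,
      schema = keypoint_schema()
    ),
    class = "dataset_bundle"
  )
  validate_bundle(bundle)
  bundle
}

validate_bundle <- function(bundle) {
  req <- c("image_id", "width", "height", "jaw")
  if (!all(req %in% names(bundle$images))) {
    stop("images table must have columns ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(bundle$images$image_id)) {
    stop("duplicate image_id in images table", call. = FALSE)
  }
  if (!all(bundle$images$jaw %in% c("upper", "lower"))) {
    stop("jaw labels must be 'upper' or 'lower'", call. = FALSE)
  }
  ids <- vapply(bundle$annotations, function(a) a$annotation_id, numeric(1))
  if (anyDuplicated(ids)) {
    stop("duplicate annotation_id in bundle", call. = FALSE)
  }
  for (ann in bundle$annotations) {
    validate_annotation(ann)
    if (!ann$image_id %in% bundle$images$image_id) {
      stop("annotation ", ann$annotation_id, " references unknown image_id ",
        ann$image_id,
        call. = FALSE
      )
    }
  }
  invisible(bundle)
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(
    "<dataset_bundle>", nrow(x$images), "images,",
    length(x$annotations), "implant annotations\n"
  )
  cat("  jaw:", paste(sprintf(
    "%s=%d", names(table(x$images$jaw)),
    as.integer(table(x$images$jaw))
  ), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.implant_prediction <- function(x, ...) {
  cat(sprintf(
    "<implant_prediction> image %s, box score %.3f, mean keypoint score %.3f\n",
    format(x$image_id), x$box_score, mean(x$keypoint_scores)
  ))
  invisible(x)
}
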