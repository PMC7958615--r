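# COCO-dialect readers/writers. Ground truth: images / annotations /
# categories with one category declaring the 6 keypoint names and a skeleton
# of 3 left-right pairs. Images additionally carry a "jaw" field. Predictions:
# COCO results records extended with a "keypoint_scores" array of 6 floats.

#' Load a ground-truth annotation file
#'
#' Reads the COCO-dialect keypoint annotation JSON: top-level `images`,
#' `annotations` and `categories`. The single category must declare the six
#' keypoint names in schema order; a file with a different order or count is
#' rejected rather than silently permuting the per-keypoint tolerances.
#' Flat 18-value keypoint arrays are regrouped into 6 `(x, y, v)` triples.
#'
#' @param path Path to the JSON file.
#' @return A [dataset_bundle()].
#' @export
#' @seealso [write_bundle()], [load_predictions()]
load_ground_truth <- function(path) {
  if (!file.exists(path)) {
    stop("ground-truth file does not exist: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse JSON at ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  for (field in c("images", "annotations", "categories")) {
    if (is.null(raw[[field]])) {
      stop("ground-truth file ", path, " lacks top-level '", field, "'",
        call. = FALSE
      )
    }
  }
  schema <- keypoint_schema()
  cat_names <- unlist(raw$categories[[1L]]$keypoints)
  if (!identical(as.character(cat_names), schema$names)) {
    stop(
      "category keypoint names/order do not match the implant schema [",
      paste(schema$names, collapse = ", "), "]",
      call. = FALSE
    )
  }
  images <- do.call(rbind, lapply(raw$images, function(im) {
    data.frame(
      image_id = as.integer(im$id),
      width = as.numeric(im$width),
      height = as.numeric(im$height),
      jaw = as.character(im$jaw)
    )
  }))
  if (is.null(images)) {
    images <- data.frame(
      image_id = integer(), width = numeric(),
      height = numeric(), jaw = character()
    )
  }
  annotations <- lapply(raw$annotations, function(a) {
    flat <- unlist(a$keypoints)
    if (length(flat) != 18L) {
      stop("annotation ", a$id, ": keypoint array has ", length(flat),
        " values, expected 18",
        call. = FALSE
      )
    }
    implant_annotation(
      annotation_id = as.integer(a$id),
      image_id = as.integer(a$image_id),
      bbox = unlist(a$bbox),
      area = a$area,
      keypoints = keypoints_from_flat(flat)
    )
  })
  dataset_bundle(images = images, annotations = annotations)
}

#' Load a prediction results file
#'
#' Reads the COCO-results-dialect JSON: an array of records, each with
#' `image_id`, `bbox`, `score`, a flat 18-value `keypoints` array and a
#' 6-value `keypoint_scores` array. Scores outside `[0, 1]` are an error,
#' never clamped.
#'
#' @param path Path to the JSON file.
#' @param bundle The already-loaded ground-truth [dataset_bundle()], used to
#'   resolve image ids.
#' @return A list of [implant_prediction()] objects.
#' @export
load_predictions <- function(path, bundle) {
  if (!file.exists(path)) {
    stop("prediction file does not exist: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse JSON at ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  lapply(raw, function(r) {
    image_id <- as.integer(r$image_id)
    if (!image_id %in% bundle$images$image_id) {
      stop("prediction references unknown image_id ", image_id, call. = FALSE)
    }
    implant_prediction(
      image_id = image_id,
      bbox = unlist(r$bbox),
      box_score = r$score,
      keypoints = keypoints_from_flat(unlist(r$keypoints)),
      keypoint_scores = unlist(r$keypoint_scores)
    )
  })
}

#' Write a ground-truth bundle back to disk
#'
#' The written file round-trips: [load_ground_truth()] on the output returns
#' a value-identical bundle. Annotations are sorted by `annotation_id` so the
#' byte stream is stable.
#'
#' @param bundle A valid [dataset_bundle()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  schema <- keypoint_schema()
  ord <- order(vapply(
    bundle$annotations,
    function(a) as.numeric(a$annotation_id), numeric(1)
  ))
  anns <- bundle$annotations[ord]
  doc <- list(
    images = lapply(seq_len(nrow(bundle$images)), function(i) {
      row <- bundle$images[i, ]
      list(
        id = row$image_id, width = row$width, height = row$height,
        jaw = row$jaw
      )
    }),
    annotations = lapply(anns, function(a) {
      list(
        id = a$annotation_id,
        image_id = a$image_id,
        category_id = 1L,
        bbox = a$bbox,
        area = a$area,
        num_keypoints = sum(a$keypoints[, "v"] > 0),
        keypoints = keypoints_to_flat(a$keypoints),
        iscrowd = 0L
      )
    }),
    categories = list(list(
      id = 1L,
      name = "implant",
      keypoints = schema$names,
      skeleton = schema$skeleton
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a prediction list to disk
#'
#' @param preds List of [implant_prediction()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(preds, path) {
  doc <- lapply(preds, function(p) {
    validate_prediction(p)
    list(
      image_id = p$image_id,
      category_id = 1L,
      bbox = p$bbox,
      score = p$box_score,
      keypoints = keypoints_to_flat(p$keypoints),
      keypoint_scores = p$keypoint_scores
    )
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
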