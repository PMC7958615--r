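# Greedy matching of detections to ground truth and the AP/AR/PR protocol
# over similarity thresholds 0.50-0.95 (step 0.05), for boxes (IoU) and
# keypoints (OKS). The protocol follows the COCO lineage: detections ranked
# by score, per-image greedy one-to-one assignment, 101-point interpolated
# average precision. Deviations from stock COCO: no maximum-detection cap
# (implant counts per radiograph are small) and the ranking score source is
# selectable, defaulting to the per-implant keypoint score because box scores
# need not track keypoint quality.

ranking_score <- function(pred, ranking, kp_aggregate = "mean") {
  switch(ranking,
    box_score = pred$box_score,
    keypoint_score = switch(kp_aggregate,
      mean = mean(pred$keypoint_scores),
      max = max(pred$keypoint_scores),
      stop("unknown keypoint score aggregation: ", kp_aggregate, call. = FALSE)
    ),
    stop("unknown ranking score source: ", ranking, call. = FALSE)
  )
}

pair_similarity <- function(gt, pred, similarity, sigma, k_constant) {
  switch(similarity,
    iou = iou(gt$bbox, pred$bbox),
    oks = oks(gt, pred$keypoints, sigma = sigma, k_constant = k_constant),
    stop("unknown similarity measure: ", similarity, call. = FALSE)
  )
}

#' Match predictions to ground truth at one similarity threshold
#'
#' Predictions are ranked by descending score (ties broken by image id then
#' input order, so replays are deterministic) and each in turn claims the
#' highest-similarity unmatched ground-truth implant on its own image with
#' similarity at or above the threshold. Matching never crosses images.
#' Unclaimed predictions are false positives; unclaimed ground truths are
#' false negatives.
#'
#' @param bundle Ground-truth [dataset_bundle()].
#' @param preds List of [implant_prediction()] objects.
#' @param similarity `"iou"` (boxes) or `"oks"` (keypoints).
#' @param threshold Similarity threshold for a true positive.
#' @param ranking Score used for ranking: `"keypoint_score"` (default; mean
#'   of the six per-keypoint confidences) or `"box_score"`.
#' @param sigma Per-keypoint tolerances for OKS; default [default_sigma()].
#' @param k_constant OKS tolerance multiplier; default 2.
#' @param kp_aggregate How to pool the six keypoint scores into one ranking
#'   score: `"mean"` (default) or `"max"`.
#' @return A data frame of class `match_set`, one row per prediction in rank
#'   order, with columns `pred_index`, `image_id`, `score`,
#'   `matched_annotation_id` (`NA` for false positives) and `similarity`;
#'   attribute `n_ground_truth` carries the ground-truth count.
#' @export
match_detections <- function(bundle, preds, similarity = c("oks", "iou"),
                             threshold, ranking = c("keypoint_score", "box_score"),
                             sigma = default_sigma(), k_constant = 2,
                             kp_aggregate = "mean") {
  similarity <- match.arg(similarity)
  ranking <- match.arg(ranking)
  img_ids <- bundle$images$image_id
  for (p in preds) {
    if (!p$image_id %in% img_ids) {
      stop("prediction references image_id ", p$image_id,
        " absent from the bundle",
        call. = FALSE
      )
    }
  }
  scores <- vapply(preds, ranking_score, numeric(1),
    ranking = ranking, kp_aggregate = kp_aggregate
  )
  pred_imgs <- vapply(preds, function(p) as.numeric(p$image_id), numeric(1))
  ord <- order(-scores, pred_imgs, seq_along(preds))
  ann_ids <- vapply(
    bundle$annotations,
    function(a) as.numeric(a$annotation_id), numeric(1)
  )
  ann_imgs <- vapply(
    bundle$annotations,
    function(a) as.numeric(a$image_id), numeric(1)
  )
  matched <- rep(FALSE, length(bundle$annotations))
  out <- data.frame(
    pred_index = ord,
    image_id = pred_imgs[ord],
    score = scores[ord],
    matched_annotation_id = rep(NA_real_, length(ord)),
    similarity = rep(NA_real_, length(ord))
  )
  for (r in seq_along(ord)) {
    p <- preds[[ord[r]]]
    cand <- which(ann_imgs == as.numeric(p$image_id) & !matched)
    if (length(cand) == 0L) next
    sims <- vapply(cand, function(ci) {
      pair_similarity(bundle$annotations[[ci]], p, similarity, sigma, k_constant)
    }, numeric(1))
    ok <- sims >= threshold
    if (!any(ok)) next
    best <- cand[ok][which.max(sims[ok])]
    matched[best] <- TRUE
    out$matched_annotation_id[r] <- ann_ids[best]
    out$similarity[r] <- max(sims[ok])
  }
  structure(out,
    n_ground_truth = length(bundle$annotations),
    similarity_threshold = threshold,
    class = c("match_set", class(out))
  )
}

#' Precision-recall curve from a match set
#'
#' Sweeps the ranking-score threshold over all distinct prediction scores
#' (descending); at each threshold the retained predictions yield
#' `precision = TP / (TP + FP)` and `recall = TP / n_ground_truth`.
#' Predictions with equal scores enter together, so equal-score ties
#' collapse to a single curve point.
#'
#' @param matches A `match_set` from [match_detections()].
#' @return Data frame of class `pr_curve` with columns `score_threshold`,
#'   `precision`, `recall`, ordered by descending threshold.
#' @export
pr_curve <- function(matches) {
  n_gt <- attr(matches, "n_ground_truth")
  if (is.null(n_gt) || n_gt == 0L) {
    stop("recall undefined: match set has no ground truth", call. = FALSE)
  }
  is_tp <- !is.na(matches$matched_annotation_id)
  cum_tp <- cumsum(is_tp)
  cum_n <- seq_len(nrow(matches))
  thresholds <- unique(matches$score)
  last_idx <- vapply(
    thresholds,
    function(t) max(which(matches$score >= t)), integer(1)
  )
  out <- data.frame(
    score_threshold = thresholds,
    precision = cum_tp[last_idx] / cum_n[last_idx],
    recall = cum_tp[last_idx] / n_gt
  )
  structure(out,
    similarity_threshold = attr(matches, "similarity_threshold"),
    n_ground_truth = n_gt,
    class = c("pr_curve", class(out))
  )
}

#' 101-point interpolated average precision
#'
#' Mean, over the recall grid \{0.00, 0.01, ..., 1.00\}, of the interpolated
#' precision `max(p(r') : r' >= r)` — zero where no curve point reaches the
#' recall level. This is the COCO-lineage convention. A tiny slack (1e-10)
#' guards the recall comparison against double-precision grid artifacts.
#'
#' @param curve A `pr_curve` (may have zero rows: AP is 0).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  if (nrow(curve) == 0L) {
    return(0)
  }
  grid <- (0:100) / 100
  ap_at <- vapply(grid, function(r) {
    reach <- curve$recall >= r - 1e-10
    if (!any(reach)) 0 else max(curve$precision[reach])
  }, numeric(1))
  mean(ap_at)
}

recall_at_all_detections <- function(matches) {
  n_gt <- attr(matches, "n_ground_truth")
  if (n_gt == 0L) {
    return(NA_real_)
  }
  sum(!is.na(matches$matched_annotation_id)) / n_gt
}

subset_bundle_jaw <- function(bundle, jaw) {
  if (jaw == "all") {
    return(bundle)
  }
  keep_imgs <- bundle$images[bundle$images$jaw == jaw, , drop = FALSE]
  keep_ids <- keep_imgs$image_id
  anns <- Filter(function(a) a$image_id %in% keep_ids, bundle$annotations)
  dataset_bundle(images = keep_imgs, annotations = anns)
}

#' Evaluate a detector over the threshold grid
#'
#' Runs matching, PR curves and AP at similarity thresholds 0.50 to 0.95 in
#' steps of 0.05 — IoU thresholds for the bounding-box task, OKS thresholds
#' for the keypoint task. `ap_all` / `ar_all` are the means over the 10
#' thresholds; AR per threshold is the recall with every prediction retained
#' (no score floor, no detection cap). Results are reported pooled and
#' stratified by jaw label.
#'
#' @inheritParams match_detections
#' @param task `"keypoints"` (OKS) or `"bbox"` (IoU).
#' @param thresholds Similarity threshold grid; default `seq(0.5, 0.95, 0.05)`.
#' @return Object of class `eval_summary`: list with `task`, `ranking`,
#'   `table` (one row per jaw x threshold with `ap`, `ar`), `summary` (one
#'   row per jaw with `ap_all`, `ap_50`, `ap_75`, `ar_all`) and `curves`
#'   (named list of `pr_curve` objects, `"<jaw>@<threshold>"`).
#' @export
evaluate <- function(bundle, preds, task = c("keypoints", "bbox"),
                     sigma = default_sigma(),
                     ranking = c("keypoint_score", "box_score"),
                     thresholds = seq(0.5, 0.95, by = 0.05),
                     k_constant = 2, kp_aggregate = "mean") {
  task <- match.arg(task)
  ranking <- match.arg(ranking)
  similarity <- if (task == "keypoints") "oks" else "iou"
  jaws <- c("all", intersect(c("upper", "lower"), unique(bundle$images$jaw)))
  rows <- list()
  curves <- list()
  for (jaw in jaws) {
    sub <- subset_bundle_jaw(bundle, jaw)
    if (length(sub$annotations) == 0L) next
    sub_preds <- Filter(function(p) p$image_id %in% sub$images$image_id, preds)
    for (t in thresholds) {
      m <- match_detections(sub, sub_preds,
        similarity = similarity, threshold = t, ranking = ranking,
        sigma = sigma, k_constant = k_constant, kp_aggregate = kp_aggregate
      )
      curve <- pr_curve(m)
      curves[[sprintf("%s@%.2f", jaw, t)]] <- curve
      rows[[length(rows) + 1L]] <- data.frame(
        jaw = jaw, threshold = t,
        ap = average_precision(curve),
        ar = recall_at_all_detections(m)
      )
    }
  }
  tab <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(tab, tab$jaw), function(d) {
    data.frame(
      jaw = d$jaw[1L],
      ap_all = mean(d$ap),
      ap_50 = d$ap[abs(d$threshold - 0.50) < 1e-9],
      ap_75 = d$ap[abs(d$threshold - 0.75) < 1e-9],
      ar_all = mean(d$ar)
    )
  }))
  rownames(summary) <- NULL
  structure(
    list(
      task = task, ranking = ranking, thresholds = thresholds,
      table = tab, summary = summary, curves = curves
    ),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> task=%s, ranking=%s, thresholds %.2f-%.2f\n",
    x$task, x$ranking, min(x$thresholds), max(x$thresholds)
  ))
  print(transform(x$summary,
    ap_all = round(ap_all, 4), ap_50 = round(ap_50, 4),
    ap_75 = round(ap_75, 4), ar_all = round(ar_all, 4)
  ))
  invisible(x)
}

#' Pooled headline numbers from an evaluation summary
#'
#' @param summary An `eval_summary`.
#' @param jaw `"all"` (default), `"upper"` or `"lower"`.
#' @return Named numeric vector `ap_all`, `ap_50`, `ap_75`, `ar_all`.
#' @export
eval_headline <- function(summary, jaw = "all") {
  row <- summary$summary[summary$summary$jaw == jaw, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("no results for jaw label '", jaw, "'", call. = FALSE)
  }
  c(
    ap_all = row$ap_all, ap_50 = row$ap_50,
    ap_75 = row$ap_75, ar_all = row$ar_all
  )
}
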