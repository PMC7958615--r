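test_that("matching handles the trivial true-positive and miss cases", {
  ann <- make_ann()
  bundle <- make_bundle(list(ann))
  pred <- make_pred(ann)
  m <- match_detections(bundle, list(pred),
    similarity = "oks", threshold = 0.5
  )
  expect_equal(sum(!is.na(m$matched_annotation_id)), 1L)
  expect_equal(attr(m, "n_ground_truth"), 1L)

  empty <- match_detections(
    make_bundle(list(make_ann(1L, 1L), make_ann(2L, 2L))), list(),
    similarity = "oks", threshold = 0.5
  )
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_ground_truth"), 2L)
})

test_that("greedy assignment agrees with brute-force enumeration on a contested GT", {
  ann <- make_ann()
  bundle <- make_bundle(list(ann))
  close_pred <- make_pred(ann, box_score = 0.9, dx = 1)
  closer_pred <- make_pred(ann, box_score = 0.6, dx = 0.1)
  m <- match_detections(bundle, list(closer_pred, close_pred),
    similarity = "oks", threshold = 0.5, ranking = "box_score"
  )
  # both exceed the threshold; brute force over the two one-to-one
  # assignments says exactly one can match, and greedy-by-score takes the
  # higher-scored prediction even though the other is geometrically closer
  expect_equal(m$score, c(0.9, 0.6))
  expect_false(is.na(m$matched_annotation_id[1]))
  expect_true(is.na(m$matched_annotation_id[2]))
})

test_that("prediction keypoints never claim a ground truth across images", {
  ann1 <- make_ann(1L, 1L)
  ann2 <- make_ann(2L, 2L, origin = c(600, 400))
  bundle <- make_bundle(list(ann1, ann2))
  stray <- make_pred(ann1)
  stray$image_id <- 2 # geometry of image 1's implant, declared on image 2
  m <- match_detections(bundle, list(stray),
    similarity = "oks", threshold = 0.5
  )
  # it may not claim image 1's implant, and image 2's sits elsewhere
  expect_true(is.na(m$matched_annotation_id))
})

test_that("pr_curve emits hand-computed precision/recall per distinct score", {
  ann <- make_ann()
  bundle <- make_bundle(list(ann))
  fp <- make_pred(ann, box_score = 0.9, dx = 500) # OKS ~ 0
  fp$bbox <- c(700, 600, 20, 20)
  tp <- make_pred(ann, box_score = 0.8)
  m <- match_detections(bundle, list(fp, tp),
    similarity = "oks", threshold = 0.5, ranking = "box_score"
  )
  curve <- pr_curve(m)
  expect_equal(curve$score_threshold, c(0.9, 0.8))
  expect_equal(curve$precision, c(0, 0.5))
  expect_equal(curve$recall, c(0, 1))
  expect_equal(average_precision(curve), 0.5)

  # all-TP fixture: precision 1 everywhere
  bundle2 <- make_bundle(list(make_ann(1L, 1L), make_ann(2L, 2L)))
  preds2 <- list(
    make_pred(bundle2$annotations[[1]], box_score = 0.7),
    make_pred(bundle2$annotations[[2]], box_score = 0.95)
  )
  curve2 <- pr_curve(match_detections(bundle2, preds2,
    similarity = "oks", threshold = 0.5, ranking = "box_score"
  ))
  expect_true(all(curve2$precision == 1))
  expect_equal(average_precision(curve2), 1)

  # equal scores collapse to a single sweep point
  preds3 <- list(
    make_pred(bundle2$annotations[[1]], box_score = 0.7),
    make_pred(bundle2$annotations[[2]], box_score = 0.7)
  )
  curve3 <- pr_curve(match_detections(bundle2, preds3,
    similarity = "oks", threshold = 0.5, ranking = "box_score"
  ))
  expect_equal(nrow(curve3), 1L)

  no_gt <- match_detections(bundle, list(tp), similarity = "oks", threshold = 0.5)
  attr(no_gt, "n_ground_truth") <- 0L
  expect_error(pr_curve(no_gt), "recall undefined")
})

test_that("average_precision implements the 101-point rule", {
  expect_equal(average_precision(structure(
    data.frame(score_threshold = 0.5, precision = 1, recall = 1),
    class = c("pr_curve", "data.frame")
  )), 1)
  expect_equal(average_precision(structure(
    data.frame(
      score_threshold = numeric(0), precision = numeric(0),
      recall = numeric(0)
    ),
    class = c("pr_curve", "data.frame")
  )), 0)
  # precision 1 up to recall 0.5 then 0.6 at recall 1:
  # envelope is 1 on grid <= 0.5 (51 points), 0.6 above (50 points)
  curve <- structure(
    data.frame(
      score_threshold = c(0.9, 0.4),
      precision = c(1, 0.6), recall = c(0.5, 1)
    ),
    class = c("pr_curve", "data.frame")
  )
  expect_equal(average_precision(curve), (51 * 1 + 50 * 0.6) / 101)
})

test_that("a perfect detector scores AP = AR = 1 on both tasks", {
  sb <- synthetic_bundle(synthetic_config(
    n_images = 6, sigma_true = rep(0, 6), fp_rate = 0, fn_rate = 0,
    box_jitter_px = 0, tp_score_range = c(1, 1), seed = 5
  ))
  for (task in c("keypoints", "bbox")) {
    res <- evaluate(sb$truth, sb$predictions, task = task)
    expect_equal(res$summary$ap_all, rep(1, nrow(res$summary)))
    expect_equal(res$summary$ar_all, rep(1, nrow(res$summary)))
  }
})

test_that("small perturbations below the 0.95-OKS bound give ap_50 = 1", {
  # at sigma_true = default/10 the displacement stays far inside every
  # threshold's tolerance, so every prediction is a TP at all thresholds
  sb <- synthetic_bundle(synthetic_config(
    n_images = 8, sigma_true = default_sigma() / 10, fp_rate = 0,
    fn_rate = 0, seed = 9
  ))
  res <- evaluate(sb$truth, sb$predictions, task = "keypoints")
  expect_equal(eval_headline(res)[["ap_50"]], 1)
})

test_that("AP and AR are non-increasing in the similarity threshold", {
  sb <- synthetic_bundle(synthetic_config(
    n_images = 10, sigma_true = default_sigma() * 2, fp_rate = 0.2,
    fn_rate = 0.1, seed = 13
  ))
  res <- evaluate(sb$truth, sb$predictions, task = "keypoints")
  tab <- res$table[res$table$jaw == "all", ]
  tab <- tab[order(tab$threshold), ]
  expect_true(all(diff(tab$ap) <= 1e-12))
  expect_true(all(diff(tab$ar) <= 1e-12))
})

test_that("removing a false positive never decreases AP", {
  set.seed(31)
  for (rep in 1:10) {
    sb <- synthetic_bundle(synthetic_config(
      n_images = 5, sigma_true = default_sigma(), fp_rate = 0.5,
      fn_rate = 0.1, seed = 300 + rep
    ))
    res <- evaluate(sb$truth, sb$predictions, task = "keypoints")
    m <- match_detections(sb$truth, sb$predictions,
      similarity = "oks", threshold = 0.5
    )
    fp_rows <- m$pred_index[is.na(m$matched_annotation_id)]
    if (length(fp_rows) == 0L) next
    drop <- sample(fp_rows, 1L)
    res2 <- evaluate(sb$truth, sb$predictions[-drop], task = "keypoints")
    expect_gte(
      eval_headline(res2)[["ap_all"]] + 1e-12,
      eval_headline(res)[["ap_all"]]
    )
  }
})

test_that("evaluate matches the independent COCO-protocol oracle", {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  for (rep in 1:5) {
    config <- synthetic_config(
      n_images = 3, implants_per_image = c(1L, 3L),
      sigma_true = default_sigma() * 2, fp_rate = 0.3, fn_rate = 0.2,
      seed = 400 + rep
    )
    sb <- synthetic_bundle(config)
    res <- evaluate(sb$truth, sb$predictions,
      task = "keypoints", ranking = "box_score"
    )
    oracle <- oracle_coco_eval(sb$truth, sb$predictions, thresholds)
    tab <- res$table[res$table$jaw == "all", ]
    tab <- tab[order(tab$threshold), ]
    expect_equal(tab$ap, oracle$ap, tolerance = 1e-6)
    expect_equal(tab$ar, oracle$ar, tolerance = 1e-6)

    res_box <- evaluate(sb$truth, sb$predictions,
      task = "bbox", ranking = "box_score"
    )
    oracle_box <- oracle_coco_eval(sb$truth, sb$predictions, thresholds,
      similarity = "iou"
    )
    tab_box <- res_box$table[res_box$table$jaw == "all", ]
    tab_box <- tab_box[order(tab_box$threshold), ]
    expect_equal(tab_box$ap, oracle_box$ap, tolerance = 1e-6)
    expect_equal(tab_box$ar, oracle_box$ar, tolerance = 1e-6)
  }
})
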