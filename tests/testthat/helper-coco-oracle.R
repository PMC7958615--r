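# Independent oracle for the detection-evaluation protocol: a from-scratch
# transcription of the published COCO evaluator algorithm, kept structurally
# different from the package implementation (flat vectors, dataset-global
# cumulative counts, backward precision envelope, grid sampling by first
# reaching index) and with its own inline similarity code. Used only to
# cross-check evaluate(); never called by package code.

oracle_sim_oks <- function(gt_flat, gt_area, dt_flat, sigmas) {
  xg <- gt_flat[seq(1, 18, 3)]
  yg <- gt_flat[seq(2, 18, 3)]
  vg <- gt_flat[seq(3, 18, 3)]
  xd <- dt_flat[seq(1, 18, 3)]
  yd <- dt_flat[seq(2, 18, 3)]
  vars <- (2 * sigmas)^2
  e <- ((xd - xg)^2 + (yd - yg)^2) / vars / gt_area / 2
  mean(exp(-e[vg > 0]))
}

oracle_sim_iou <- function(g, d) {
  ix <- min(g[1] + g[3], d[1] + d[3]) - max(g[1], d[1])
  iy <- min(g[2] + g[4], d[2] + d[4]) - max(g[2], d[2])
  inter <- max(0, ix) * max(0, iy)
  inter / (g[3] * g[4] + d[3] * d[4] - inter)
}

# returns per-threshold ap and ar for the pooled ("all") stratum
oracle_coco_eval <- function(bundle, preds, thresholds,
                             similarity = "oks", sigmas = default_sigma()) {
  n_thr <- length(thresholds)
  npig <- length(bundle$annotations)
  all_scores <- numeric(0)
  all_matched <- matrix(numeric(0), nrow = n_thr, ncol = 0)
  for (img in bundle$images$image_id) {
    gts <- Filter(function(a) a$image_id == img, bundle$annotations)
    dts <- Filter(function(p) p$image_id == img, preds)
    if (length(dts) == 0L) next
    scores <- vapply(dts, function(p) p$box_score, numeric(1))
    dt_ord <- order(-scores)
    sim <- matrix(0, length(dts), max(1L, length(gts)))
    for (di in seq_along(dts)) {
      for (gi in seq_along(gts)) {
        sim[di, gi] <- if (similarity == "oks") {
          oracle_sim_oks(
            keypoints_to_flat(gts[[gi]]$keypoints), gts[[gi]]$area,
            keypoints_to_flat(dts[[di]]$keypoints), sigmas
          )
        } else {
          oracle_sim_iou(gts[[gi]]$bbox, dts[[di]]$bbox)
        }
      }
    }
    matched <- matrix(0, n_thr, length(dts))
    for (ti in seq_len(n_thr)) {
      gtm <- rep(FALSE, length(gts))
      for (di in dt_ord) {
        floor_sim <- min(thresholds[ti], 1 - 1e-10)
        m <- -1L
        for (gi in seq_along(gts)) {
          if (gtm[gi]) next
          if (sim[di, gi] < floor_sim) next
          floor_sim <- sim[di, gi]
          m <- gi
        }
        if (m > 0L) {
          gtm[m] <- TRUE
          matched[ti, di] <- 1
        }
      }
    }
    all_scores <- c(all_scores, scores)
    all_matched <- cbind(all_matched, matched)
  }
  ap <- numeric(n_thr)
  ar <- numeric(n_thr)
  if (length(all_scores) > 0L) {
    ord <- order(-all_scores)
    rec_grid <- (0:100) / 100
    for (ti in seq_len(n_thr)) {
      tp <- cumsum(all_matched[ti, ord])
      fp <- cumsum(1 - all_matched[ti, ord])
      rc <- tp / npig
      pr <- tp / (tp + fp)
      ar[ti] <- if (length(rc) > 0L) rc[length(rc)] else 0
      for (i in rev(seq_len(length(pr) - 1L))) {
        if (pr[i] < pr[i + 1L]) pr[i] <- pr[i + 1L]
      }
      q <- vapply(rec_grid, function(r) {
        hit <- which(rc >= r - 1e-10)
        if (length(hit) == 0L) 0 else pr[hit[1L]]
      }, numeric(1))
      ap[ti] <- mean(q)
    }
  }
  list(ap = ap, ar = ar, thresholds = thresholds)
}
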