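# Mean-OKS observer agreement: the confidence-score-free summary that lets a
# detector be compared with a human annotator, plus the analytic normal-model
# reading of a mean OKS and the dentist-vs-model independent t-test.

#' Mean OKS of valid detections
#'
#' Keeps the predictions whose detection (box) confidence is strictly above
#' `detection_threshold`, pairs them one-to-one with ground-truth implants on
#' the same image by greedily taking the highest-OKS pair (ties broken by
#' prediction order), and averages the OKS of the matched pairs. Unlike the
#' AP/AR protocol this uses a single fixed threshold, so the same number can
#' be computed for a human annotator who provides no confidence scores.
#' Implants whose ground truth has no labeled keypoint are excluded (their
#' OKS is undefined), never scored 0.
#'
#' @param bundle Ground-truth [dataset_bundle()].
#' @param preds List of [implant_prediction()] objects.
#' @param sigma Per-keypoint tolerances; default [default_sigma()].
#' @param detection_threshold Box-score validity threshold in `[0, 1]`;
#'   default 0.7.
#' @param k_constant OKS tolerance multiplier; default 2.
#' @return Object of class `agreement_report`: list with `oks_values` (one
#'   per matched implant), `mean_oks`, `n_detected`, `detection_threshold`
#'   and `sigma` (recorded so two reports are only compared under identical
#'   tolerances).
#' @export
mean_oks <- function(bundle, preds, sigma = default_sigma(),
                     detection_threshold = 0.7, k_constant = 2) {
  if (detection_threshold < 0 || detection_threshold > 1) {
    stop("detection_threshold must lie in [0, 1]", call. = FALSE)
  }
  keep <- vapply(
    preds, function(p) p$box_score > detection_threshold,
    logical(1)
  )
  valid <- preds[keep]
  if (length(valid) == 0L) {
    stop("no predictions survive the detection threshold ",
      detection_threshold, "; agreement report would be empty",
      call. = FALSE
    )
  }
  scorable <- Filter(
    function(a) any(a$keypoints[, "v"] > 0),
    bundle$annotations
  )
  ann_imgs <- vapply(scorable, function(a) as.numeric(a$image_id), numeric(1))
  pred_imgs <- vapply(valid, function(p) as.numeric(p$image_id), numeric(1))
  # all candidate pairs on shared images, greedily consumed by OKS
  pairs <- list()
  for (pi in seq_along(valid)) {
    for (ai in which(ann_imgs == pred_imgs[pi])) {
      pairs[[length(pairs) + 1L]] <- c(
        pi, ai,
        oks(scorable[[ai]], valid[[pi]]$keypoints,
          sigma = sigma, k_constant = k_constant
        )
      )
    }
  }
  oks_values <- numeric(0)
  if (length(pairs) > 0L) {
    tab <- do.call(rbind, pairs)
    ord <- order(-tab[, 3L], tab[, 1L])
    tab <- tab[ord, , drop = FALSE]
    used_p <- logical(length(valid))
    used_a <- logical(length(scorable))
    for (r in seq_len(nrow(tab))) {
      pi <- tab[r, 1L]
      ai <- tab[r, 2L]
      if (used_p[pi] || used_a[ai]) next
      used_p[pi] <- TRUE
      used_a[ai] <- TRUE
      oks_values <- c(oks_values, tab[r, 3L])
    }
  }
  structure(
    list(
      oks_values = oks_values,
      mean_oks = mean(oks_values),
      n_detected = length(valid),
      detection_threshold = detection_threshold,
      sigma = as.numeric(sigma)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> mean OKS %.4f over %d matched implants (%d detections above %.2f)\n",
    x$mean_oks, length(x$oks_values), x$n_detected, x$detection_threshold
  ))
  invisible(x)
}

#' Invert a single-keypoint OKS to an equivalent displacement multiplier
#'
#' The individual keypoint similarity is `exp(-d^2 / (2 s^2 k^2))` with
#' `k = 2 * sigma`. Solving for the displacement at a given similarity gives
#' `d / s = m * sigma` with `m = sqrt(-8 * log(oks_value))`: the equivalent
#' displacement expressed in multiples of the human annotation SD. A mean
#' OKS of 0.8885 inverts to m of about 0.9725.
#'
#' @param oks_value OKS in `(0, 1]`.
#' @return Non-negative multiplier `m`.
#' @export
#' @examples
#' oks_to_sigma_multiplier(0.8885)
oks_to_sigma_multiplier <- function(oks_value) {
  if (any(!is.finite(oks_value)) || any(oks_value <= 0) || any(oks_value > 1)) {
    stop("oks_value must lie in (0, 1]", call. = FALSE)
  }
  sqrt(-8 * log(oks_value))
}

#' Share of human annotations expected to beat a given OKS
#'
#' Treats the signed one-dimensional projection of human annotation error,
#' after scaling by `s * sigma_i`, as standard normal. A detector whose mean
#' OKS corresponds to a displacement of `m * sigma_i * s` then sits at the
#' `2 * Phi(m) - 1` quantile of absolute human error: that fraction of human
#' annotations lies closer to ground truth than the detector's equivalent
#' displacement. Returned as a percentage. At mean OKS 0.8885 this is about
#' 66.92%.
#'
#' @param oks_value OKS in `(0, 1]`.
#' @return Percentage in `[0, 100)`.
#' @export
#' @examples
#' fraction_better(0.8885)
fraction_better <- function(oks_value) {
  m <- oks_to_sigma_multiplier(oks_value)
  100 * (2 * stats::pnorm(m) - 1)
}

#' Independent t-test between two observers' OKS values
#'
#' Compares per-implant OKS values of two observers (e.g. a dentist and a
#' detector) with a two-sample, two-sided t-test. Welch's unequal-variance
#' form is the default; the pooled-variance Student form is available. The
#' t statistic is signed as group A minus group B.
#'
#' @param oks_a,oks_b Numeric vectors of per-implant OKS values, each of
#'   length at least 2.
#' @param method `"welch"` (default) or `"pooled"`.
#' @return Object of class `comparison_result`: list with `t`, `df`,
#'   `p_value`, `method`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_observers <- function(oks_a, oks_b, method = c("welch", "pooled")) {
  method <- match.arg(method)
  if (length(oks_a) < 2L || length(oks_b) < 2L) {
    stop("each group needs at least 2 OKS values", call. = FALSE)
  }
  if (stats::var(oks_a) == 0 && stats::var(oks_b) == 0) {
    # both groups constant (e.g. two perfect observers): the test statistic
    # is 0/0; report no evidence of a difference when the means agree, and
    # certainty when they do not
    equal <- mean(oks_a) == mean(oks_b)
    fit <- list(
      statistic = if (equal) 0 else sign(mean(oks_a) - mean(oks_b)) * Inf,
      parameter = length(oks_a) + length(oks_b) - 2,
      p.value = if (equal) 1 else 0
    )
    return(structure(
      list(
        t = fit$statistic, df = fit$parameter, p_value = fit$p.value,
        method = method,
        n_a = length(oks_a), n_b = length(oks_b),
        mean_a = mean(oks_a), mean_b = mean(oks_b)
      ),
      class = "comparison_result"
    ))
  }
  fit <- stats::t.test(oks_a, oks_b, var.equal = (method == "pooled"))
  structure(
    list(
      t = unname(fit$statistic),
      df = unname(fit$parameter),
      p_value = unname(fit$p.value),
      method = method,
      n_a = length(oks_a), n_b = length(oks_b),
      mean_a = mean(oks_a), mean_b = mean(oks_b)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s t = %.4f, df = %.2f, p = %.4g (means %.4f vs %.4f)\n",
    x$method, x$t, x$df, x$p_value, x$mean_a, x$mean_b
  ))
  invisible(x)
}
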