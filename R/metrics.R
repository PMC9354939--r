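## Detection evaluation (precision / recall / F1 / average precision) and
## manual-vs-system agreement statistics (R^2, MAPE, RMSE).

#' Match detections against ground-truth boxes
#'
#' Greedy matching in descending detection score (ties broken by `x0`, then
#' `y0`): each detection claims the unmatched ground-truth box with the
#' highest IoU (ties broken by ground-truth index) and is a true positive
#' when that IoU reaches `iou_min`; each ground-truth box is matched at
#' most once. Unmatched detections are false positives, unmatched
#' ground-truth boxes false negatives.
#'
#' @param detections data.frame with `x0, y0, x1, y1` and optional `score`.
#' @param ground_truth data.frame or matrix of ground-truth boxes
#'   (`x0, y0, x1, y1`).
#' @param iou_min Minimum IoU for a positive match (default 0.5).
#' @return List with `tp`, `fp`, `fn` and `pairs` (data.frame of
#'   `det_index`, `gt_index`, `iou`, indices into the *input* order).
#' @export
match_detections <- function(detections, ground_truth, iou_min = 0.5) {
  det <- as_detections(detections)
  gt <- gt_boxes(ground_truth)
  n_det <- nrow(det); n_gt <- nrow(gt)
  if (n_det == 0L || n_gt == 0L) {
    return(list(tp = 0L, fp = n_det, fn = n_gt, pairs = empty_pairs()))
  }
  ord <- order(-det$score, det$x0, det$y0)
  boxes <- as.matrix(det[, c("x0", "y0", "x1", "y1")])
  taken <- logical(n_gt)
  pairs <- vector("list", n_det)
  for (k in seq_along(ord)) {
    i <- ord[k]
    free <- which(!taken)
    if (!length(free)) break
    ious <- iou_one_many(boxes[i, ], gt[free, , drop = FALSE])
    best <- free[order(-ious, free)[1]]
    best_iou <- max(ious)
    if (best_iou >= iou_min) {
      taken[best] <- TRUE
      pairs[[k]] <- data.frame(det_index = i, gt_index = best, iou = best_iou)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) pairs <- empty_pairs()
  tp <- nrow(pairs)
  list(tp = tp, fp = n_det - tp, fn = n_gt - tp, pairs = pairs)
}

empty_pairs <- function() {
  data.frame(det_index = integer(0), gt_index = integer(0), iou = numeric(0))
}

gt_boxes <- function(ground_truth) {
  if (is.null(ground_truth)) return(matrix(numeric(0), 0, 4))
  if (is.data.frame(ground_truth)) {
    if (!all(c("x0", "y0", "x1", "y1") %in% names(ground_truth))) {
      stopf("ground truth needs columns x0, y0, x1, y1")
    }
    ground_truth <- as.matrix(ground_truth[, c("x0", "y0", "x1", "y1")])
  }
  if (!is.matrix(ground_truth) || ncol(ground_truth) != 4) {
    stopf("ground truth must be boxes (n x 4)")
  }
  if (nrow(ground_truth) &&
        (any(ground_truth[, 3] <= ground_truth[, 1]) ||
           any(ground_truth[, 4] <= ground_truth[, 2]))) {
    stopf("ground truth contains degenerate boxes")
  }
  ground_truth
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`. Undefined quantities (no detections, no ground
#' truth, or `P = R = 0`) are returned as `NA`, never as 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(tp = 8, fp = 2, fn = 2)  # P = R = F1 = 0.8
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (!is_count(tp) || !is_count(fp) || !is_count(fn)) {
    stopf("tp, fp, fn must be non-negative counts")
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' F1 from precision and recall values
#'
#' Harmonic mean of precision and recall, for use with already-computed
#' rates (e.g. published per-variety results).
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return F1 value.
#' @export
f1_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    stopf("precision and recall must lie in [0, 1]")
  }
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Average precision over a scored detection set
#'
#' Detections are swept from the highest score down, accumulating true and
#' false positives with the greedy matching of [match_detections()] (the
#' greedy assignment of the top-k detections is a prefix of the full
#' assignment, so one pass suffices). AP is the all-points area under the
#' precision-recall curve, `sum((r_k - r_(k-1)) * p_k)` - the direct
#' discretisation of the integral of P(r) over recall - with an optional
#' interpolated variant that first replaces precision by its running
#' maximum from the right.
#'
#' @param detections Scored detections data.frame.
#' @param ground_truth Ground-truth boxes.
#' @param iou_min Minimum IoU for a positive (default 0.5).
#' @param interpolate Use the interpolated-precision envelope (default
#'   `FALSE`: plain all-points integration).
#' @return List with `ap` and `pr_curve` (data.frame `recall`, `precision`,
#'   `score`; recall is non-decreasing). `ap` is `NA` when there is no
#'   ground truth.
#' @export
average_precision <- function(detections, ground_truth, iou_min = 0.5,
                              interpolate = FALSE) {
  det <- as_detections(detections)
  gt <- gt_boxes(ground_truth)
  n_gt <- nrow(gt)
  if (n_gt == 0L) {
    return(list(ap = NA_real_, pr_curve = data.frame(
      recall = numeric(0), precision = numeric(0), score = numeric(0)
    )))
  }
  if (nrow(det) == 0L) {
    return(list(ap = 0, pr_curve = data.frame(
      recall = 0, precision = NA_real_, score = NA_real_
    )))
  }
  ord <- order(-det$score, det$x0, det$y0)
  det <- det[ord, , drop = FALSE]
  boxes <- as.matrix(det[, c("x0", "y0", "x1", "y1")])
  taken <- logical(n_gt)
  is_tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    free <- which(!taken)
    if (!length(free)) break
    ious <- iou_one_many(boxes[i, ], gt[free, , drop = FALSE])
    if (max(ious) >= iou_min) {
      taken[free[order(-ious, free)[1]]] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  ctp <- cumsum(is_tp)
  cfp <- cumsum(!is_tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  p_used <- precision
  if (interpolate) p_used <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * p_used)
  list(
    ap = ap,
    pr_curve = data.frame(recall = recall, precision = precision,
                          score = det$score)
  )
}

#' Agreement between system and manual measurements
#'
#' For paired vectors of system measurements `x_a` and manual (ground
#' truth) measurements `x_m`:
#' \deqn{R^2 = \sum (x_{ai} - \bar x_m)^2 / \sum (x_{mi} - \bar x_m)^2}
#' \deqn{MAPE = (1/n) \sum |x_{ai} - x_{mi}| / x_{mi}}
#' \deqn{RMSE = \sqrt{(1/n) \sum (x_{ai} - x_{mi})^2}}
#' The ratio-of-scatter form of \eqn{R^2} above can exceed 1 when the system
#' values spread more widely about the manual mean than the manual values
#' do, so the standard squared Pearson correlation is reported alongside it
#' as `r2_pearson`.
#'
#' @param system,manual Equal-length numeric vectors (n >= 1); `manual`
#'   must be nonzero everywhere for MAPE and non-constant (n >= 2) for R^2.
#' @return An `agreement_report`: `n`, `r2` (ratio-of-scatter form),
#'   `r2_pearson`, `mape` (fraction), `mape_pct`, `rmse`.
#' @examples
#' agreement_stats(c(11, 19), c(10, 20))  # MAPE 0.075, RMSE 1
#' @export
agreement_stats <- function(system, manual) {
  if (length(system) != length(manual) || !length(system)) {
    stopf("system and manual must be equal-length, non-empty vectors")
  }
  if (anyNA(system) || anyNA(manual)) stopf("measurements must not be NA")
  n <- length(system)
  if (any(manual == 0)) {
    stopf("MAPE is undefined: manual measurements contain zero")
  }
  if (n < 2 || stats::var(manual) == 0) {
    stopf("R^2 is undefined for a constant manual vector (need n >= 2)")
  }
  mbar <- mean(manual)
  r2 <- sum((system - mbar)^2) / sum((manual - mbar)^2)
  r2_pearson <- if (stats::var(system) == 0) {
    NA_real_
  } else {
    stats::cor(system, manual)^2
  }
  mape <- mean(abs(system - manual) / manual)
  rmse <- sqrt(mean((system - manual)^2))
  structure(
    list(n = n, r2 = r2, r2_pearson = r2_pearson,
         mape = mape, mape_pct = 100 * mape, rmse = rmse),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("Agreement over %d pairs: R^2 %.3f (scatter-ratio), ",
           "%.3f (Pearson); MAPE %.2f%%; RMSE %.3f\n"),
    x$n, x$r2, if (is.na(x$r2_pearson)) NA else x$r2_pearson,
    x$mape_pct, x$rmse
  ))
  invisible(x)
}
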