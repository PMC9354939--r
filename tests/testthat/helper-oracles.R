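## Independent reference implementations used as oracles. These are kept
## deliberately naive (scalar loops, exhaustive enumeration) and separate
## from the package code paths they check.

## Render an ellipse on its own canvas by brute-force pixel membership.
oracle_render_ellipse <- function(h, w, cx, cy, a, b, theta, level = 255,
                                  bg = 0) {
  canvas <- matrix(bg, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      dx <- (cc - 1) - cx
      dy <- (r - 1) - cy
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      v <- (-dx * sin(theta) + dy * cos(theta)) / b
      if (u * u + v * v <= 1) canvas[r, cc] <- level
    }
  }
  canvas
}

## Scalar bilinear sampler matching the RoIAlign convention: value (r, c)
## sits at (c - 0.5, r - 0.5), border-clamped.
oracle_bilinear <- function(fm, x, y) {
  h <- nrow(fm); w <- ncol(fm)
  gx <- min(max(x - 0.5, 0), w - 1)
  gy <- min(max(y - 0.5, 0), h - 1)
  x0 <- min(floor(gx), w - 1); x1 <- min(x0 + 1, w - 1)
  y0 <- min(floor(gy), h - 1); y1 <- min(y0 + 1, h - 1)
  fx <- gx - x0; fy <- gy - y0
  fm[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
    fm[y0 + 1, x1 + 1] * (1 - fy) * fx +
    fm[y1 + 1, x0 + 1] * fy * (1 - fx) +
    fm[y1 + 1, x1 + 1] * fy * fx
}

oracle_roi_align <- function(fm, roi, out_h, out_w, s) {
  bw <- (roi[3] - roi[1]) / out_w
  bh <- (roi[4] - roi[2]) / out_h
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      acc <- 0
      for (si in seq_len(s)) {
        for (sj in seq_len(s)) {
          x <- roi[1] + (j - 1 + (sj - 0.5) / s) * bw
          y <- roi[2] + (i - 1 + (si - 0.5) / s) * bh
          acc <- acc + oracle_bilinear(fm, x, y)
        }
      }
      out[i, j] <- acc / (s * s)
    }
  }
  out
}

oracle_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

## O(n^2) greedy NMS with the same deterministic ordering.
oracle_nms <- function(det, thresh) {
  ord <- order(-det$score, det$x0, det$y0)
  det <- det[ord, , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(det))) {
    b <- as.numeric(det[i, c("x0", "y0", "x1", "y1")])
    ok <- TRUE
    for (k in kept) {
      if (oracle_iou(b, k) > thresh) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1]] <- b
  }
  do.call(rbind, kept)
}

## Greedy score-ordered matcher, written independently with explicit loops.
oracle_match <- function(det, gt, iou_min) {
  ord <- order(-det$score, det$x0, det$y0)
  taken <- rep(FALSE, nrow(gt))
  tp <- 0
  for (i in ord) {
    b <- as.numeric(det[i, c("x0", "y0", "x1", "y1")])
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(gt))) {
      if (taken[j]) next
      v <- oracle_iou(b, as.numeric(gt[j, ]))
      if (v > best + 1e-12) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= iou_min) {
      taken[best_j] <- TRUE
      tp <- tp + 1
    }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(gt) - tp)
}

## AP by exhaustive enumeration of score cutoffs: for each k, match the
## top-k detections from scratch and integrate P over the recall steps.
oracle_ap <- function(det, gt, iou_min) {
  ord <- order(-det$score, det$x0, det$y0)
  det <- det[ord, , drop = FALSE]
  prev_r <- 0; ap <- 0
  for (k in seq_len(nrow(det))) {
    m <- oracle_match(det[seq_len(k), , drop = FALSE], gt, iou_min)
    r <- m$tp / nrow(gt)
    p <- m$tp / k
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

oracle_agreement <- function(system, manual) {
  n <- length(manual)
  mbar <- sum(manual) / n
  num <- 0; den <- 0; mape <- 0; sse <- 0
  for (i in seq_len(n)) {
    num <- num + (system[i] - mbar)^2
    den <- den + (manual[i] - mbar)^2
    mape <- mape + abs(system[i] - manual[i]) / manual[i]
    sse <- sse + (system[i] - manual[i])^2
  }
  list(r2 = num / den, mape = mape / n, rmse = sqrt(sse / n))
}

## Random valid box helper for property tests.
random_boxes <- function(n, extent = 100, min_side = 2, max_side = 30) {
  x0 <- runif(n, 0, extent - max_side)
  y0 <- runif(n, 0, extent - max_side)
  data.frame(
    x0 = x0, y0 = y0,
    x1 = x0 + runif(n, min_side, max_side),
    y1 = y0 + runif(n, min_side, max_side),
    score = round(runif(n), 3),
    label = "grain", stringsAsFactors = FALSE
  )
}

## Small scene spec used across tests.
small_spec <- function(n_isolated = 5, n_clusters = 0, n_impurities = 0,
                       ...) {
  scene_spec(frame_width = 512, frame_height = 256, n_frames = 2,
             n_isolated = n_isolated, n_clusters = n_clusters,
             n_impurities = n_impurities, ...)
}
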