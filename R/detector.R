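## Building blocks of the two-stage threshed-panicle detector: anchor
## generation with grain-sized scales, IoU, quantization-free RoIAlign
## pooling, squeeze-and-excitation channel gating, greedy NMS, and residual
## spikelet counting above a confidence threshold. A classical ellipse-based
## detector backs the same interface so the end-to-end pipeline runs without
## trained weights.

#' Anchor configuration
#'
#' Anchors per feature-map cell are the cross product of `scales` (box
#' areas) and `ratios` (height:width). The defaults are the grain-sized
#' scales 32^2, 64^2 and 128^2 with ratios 1:1, 1:2 and 2:1 - nine anchors
#' per position - chosen because a spikelet occupies roughly 30 x 60 px in
#' a 2,048-px-wide panicle image, far smaller than the generic detector
#' scales 128^2-512^2.
#'
#' @param scales Numeric vector of anchor areas in px^2.
#' @param ratios Numeric vector of height/width ratios.
#' @param stride Feature-map stride in image pixels.
#' @return An object of class `anchor_config`.
#' @export
anchor_config <- function(scales = c(32^2, 64^2, 128^2),
                          ratios = c(1, 0.5, 2), stride = 16) {
  if (any(scales <= 0) || any(ratios <= 0) || stride <= 0) {
    stopf("scales, ratios and stride must be positive")
  }
  structure(list(scales = scales, ratios = ratios, stride = stride),
            class = "anchor_config")
}

#' Generate anchors over a feature map
#'
#' Each feature cell (i, j) contributes `length(scales) * length(ratios)`
#' anchors centred on the cell centre in image coordinates,
#' `((j + 0.5) * stride, (i + 0.5) * stride)`. Box sides are
#' `w = round(sqrt(scale / ratio))`, `h = round(w * ratio)`.
#'
#' @param cfg An [anchor_config()].
#' @param feature_h,feature_w Feature-map height and width in cells.
#' @return Matrix with `feature_h * feature_w * n_anchor` rows and columns
#'   `x0, y0, x1, y1` (half-open image coordinates).
#' @examples
#' nrow(generate_anchors(anchor_config(), 1, 1))  # 9
#' @export
generate_anchors <- function(cfg, feature_h, feature_w) {
  stopifnot(inherits(cfg, "anchor_config"))
  if (!is_count(feature_h) || !is_count(feature_w) ||
        feature_h < 1 || feature_w < 1) {
    stopf("feature dimensions must be positive integers")
  }
  combos <- expand.grid(scale = cfg$scales, ratio = cfg$ratios)
  w <- round(sqrt(combos$scale / combos$ratio))
  h <- round(w * combos$ratio)
  cells <- expand.grid(j = seq_len(feature_w) - 1L,
                       i = seq_len(feature_h) - 1L)
  cx <- rep((cells$j + 0.5) * cfg$stride, each = nrow(combos))
  cy <- rep((cells$i + 0.5) * cfg$stride, each = nrow(combos))
  ww <- rep(w, times = nrow(cells))
  hh <- rep(h, times = nrow(cells))
  out <- cbind(x0 = cx - ww / 2, y0 = cy - hh / 2,
               x1 = cx + ww / 2, y1 = cy + hh / 2)
  rownames(out) <- NULL
  out
}

#' Intersection over union of axis-aligned boxes
#'
#' Continuous box geometry on half-open boxes `c(x0, y0, x1, y1)`; both
#' arguments may be single boxes or n x 4 matrices (broadcast pairwise when
#' one side is a single box, elementwise when both are matrices of equal
#' height).
#'
#' @param a,b Boxes.
#' @return IoU value(s) in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
box_iou <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stopf("incompatible box counts")
  for (i in seq_len(nrow(a))) {
    check_box(a[i, ], "boxA")
    check_box(b[i, ], "boxB")
  }
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  out <- inter / (areaA + areaB - inter)
  unname(out)
}

## IoU of one box against an n x 4 matrix, without validation overhead.
iou_one_many <- function(box, boxes) {
  iw <- pmax(0, pmin(box[3], boxes[, 3]) - pmax(box[1], boxes[, 1]))
  ih <- pmax(0, pmin(box[4], boxes[, 4]) - pmax(box[2], boxes[, 2]))
  inter <- iw * ih
  area <- (box[3] - box[1]) * (box[4] - box[2])
  areas <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  inter / (area + areas - inter)
}

#' RoIAlign: quantization-free region-of-interest pooling
#'
#' Pools a region of a feature map into an `output_size` grid without any
#' coordinate rounding: each output bin averages `samples_per_bin^2`
#' bilinearly interpolated feature values taken at exact sub-pixel
#' locations. (RoIPool, by contrast, snaps both the region and the bin
#' edges to the integer grid, and the resulting shift is what misplaces
#' small, close-packed grain boxes.) Feature value (r, c) sits at
#' continuous location `(c - 0.5, r - 0.5)` in 0-based coordinates;
#' sampling outside the map clamps to the border.
#'
#' @param feature_map Numeric matrix (one channel).
#' @param roi_box Region `c(x0, y0, x1, y1)` in feature-map coordinates,
#'   within the map extent.
#' @param output_size `c(rows, cols)` of the pooled grid (or one integer).
#' @param samples_per_bin Sampling density per bin side.
#' @return `output_size` matrix of pooled values.
#' @export
roi_align <- function(feature_map, roi_box, output_size = c(7, 7),
                      samples_per_bin = 2L) {
  if (!is.matrix(feature_map)) stopf("feature_map must be a matrix")
  if (length(output_size) == 1L) output_size <- rep(output_size, 2L)
  if (any(output_size < 1) || samples_per_bin < 1) {
    stopf("output_size and samples_per_bin must be >= 1")
  }
  check_box(roi_box, "roi_box")
  h <- nrow(feature_map); w <- ncol(feature_map)
  if (roi_box[1] < 0 || roi_box[2] < 0 || roi_box[3] > w || roi_box[4] > h) {
    stopf("roi_box must lie within the feature map extent")
  }
  oh <- output_size[1]; ow <- output_size[2]
  bw <- (roi_box[3] - roi_box[1]) / ow
  bh <- (roi_box[4] - roi_box[2]) / oh
  s <- samples_per_bin
  offs <- (seq_len(s) - 0.5) / s
  ## All sample coordinates at once: ow*s columns x oh*s rows.
  sx <- roi_box[1] + as.vector(outer(offs, seq_len(ow) - 1L, "+")) * bw
  sy <- roi_box[2] + as.vector(outer(offs, seq_len(oh) - 1L, "+")) * bh
  vals <- bilinear_grid(feature_map, sx, sy)   # length(sy) x length(sx)
  ## Average s x s blocks.
  col_group <- rep(seq_len(ow), each = s)
  row_group <- rep(seq_len(oh), each = s)
  pooled <- rowsum(vals, row_group, reorder = TRUE)
  pooled <- t(rowsum(t(pooled), col_group, reorder = TRUE)) / (s * s)
  matrix(pooled, oh, ow)
}

## Bilinear interpolation of `fm` on the grid sx x sy (vectors of continuous
## coordinates; value (r, c) lives at (c - 0.5, r - 0.5)); border-clamped.
bilinear_grid <- function(fm, sx, sy) {
  h <- nrow(fm); w <- ncol(fm)
  gx <- clamp(sx - 0.5, 0, w - 1)
  gy <- clamp(sy - 0.5, 0, h - 1)
  x0 <- pmin(floor(gx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  y0 <- pmin(floor(gy), h - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- gx - x0
  fy <- gy - y0
  ## Outer combination of row weights and column weights.
  v00 <- fm[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
  v01 <- fm[cbind(rep(y0 + 1, length(x1)), rep(x1 + 1, each = length(y0)))]
  v10 <- fm[cbind(rep(y1 + 1, length(x0)), rep(x0 + 1, each = length(y1)))]
  v11 <- fm[cbind(rep(y1 + 1, length(x1)), rep(x1 + 1, each = length(y1)))]
  dim(v00) <- dim(v01) <- dim(v10) <- dim(v11) <- c(length(sy), length(sx))
  wy <- matrix(fy, length(sy), length(sx))
  wx <- matrix(fx, length(sy), length(sx), byrow = TRUE)
  v00 * (1 - wy) * (1 - wx) + v01 * (1 - wy) * wx +
    v10 * wy * (1 - wx) + v11 * wy * wx
}

#' Squeeze-and-excitation channel attention
#'
#' Per channel, the squeeze merges global average pooling and global max
#' pooling (elementwise sum by default, or concatenation); a two-layer
#' bottleneck (`relu` then `sigmoid`) turns the squeezed vector into one
#' gate per channel in (0, 1), and each channel is rescaled by its gate.
#'
#' @param x Numeric array `h x w x C`.
#' @param W1 Matrix `(C / reduction) x C` (or `x 2C` for `merge = "concat"`).
#' @param W2 Matrix `C x (C / reduction)`.
#' @param merge How to merge average and max pooling: `"sum"` or `"concat"`.
#' @return List with `output` (gated array, same shape as `x`) and `gates`
#'   (length-C vector in (0, 1)).
#' @examples
#' x <- array(1, c(2, 2, 4))
#' z <- se_attention(x, matrix(0, 2, 4), matrix(0, 4, 2))
#' z$gates  # all 0.5 with zero weights
#' @export
se_attention <- function(x, W1, W2, merge = c("sum", "concat")) {
  merge <- match.arg(merge)
  if (length(dim(x)) != 3L) stopf("x must be an h x w x C array")
  C <- dim(x)[3]
  avg <- apply(x, 3, mean)
  mx <- apply(x, 3, max)
  s <- if (merge == "sum") avg + mx else c(avg, mx)
  if (ncol(W1) != length(s)) {
    stopf("W1 has %d columns but the squeeze vector has length %d",
          ncol(W1), length(s))
  }
  if (nrow(W2) != C || ncol(W2) != nrow(W1)) {
    stopf("W2 must be C x nrow(W1)")
  }
  z <- pmax(as.vector(W1 %*% s), 0)
  gates <- 1 / (1 + exp(-as.vector(W2 %*% z)))
  out <- sweep(x, 3, gates, "*")
  list(output = out, gates = gates)
}

#' Deterministic random initialisation of SE weights
#'
#' @param channels Number of channels C.
#' @param reduction Bottleneck reduction ratio (default 16); `channels`
#'   must be at least `reduction`.
#' @param merge Squeeze merge mode, as in [se_attention()].
#' @param seed RNG seed.
#' @return List with `W1` and `W2`.
#' @export
se_init_weights <- function(channels, reduction = 16, merge = c("sum", "concat"),
                            seed = 1L) {
  merge <- match.arg(merge)
  if (channels < reduction) stopf("channels must be >= reduction")
  hidden <- max(1L, channels %/% reduction)
  in_dim <- if (merge == "sum") channels else 2L * channels
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(hidden * in_dim, 0, 1 / sqrt(in_dim)),
                hidden, in_dim),
    W2 = matrix(stats::rnorm(channels * hidden, 0, 1 / sqrt(hidden)),
                channels, hidden)
  ))
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in descending score (ties broken by `x0`, then
#' `y0`, so the result is deterministic); a detection is suppressed when its
#' IoU with an already-kept detection exceeds `iou_thresh`.
#'
#' @param detections data.frame with `x0, y0, x1, y1, score`.
#' @param iou_thresh Suppression threshold (strict `>`).
#' @return The kept detections, in kept (descending score) order.
#' @export
nms <- function(detections, iou_thresh = 0.5) {
  det <- as_detections(detections)
  if (nrow(det) <= 1L) return(det)
  ord <- order(-det$score, det$x0, det$y0)
  det <- det[ord, , drop = FALSE]
  boxes <- as.matrix(det[, c("x0", "y0", "x1", "y1")])
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(det)) {
      rest <- which(alive & seq_len(nrow(det)) > i)
      if (length(rest)) {
        ious <- iou_one_many(boxes[i, ], boxes[rest, , drop = FALSE])
        alive[rest[ious > iou_thresh]] <- FALSE
      }
    }
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count residual spikelets on a threshed panicle (TPSN)
#'
#' The threshed-panicle spikelet number is the number of post-NMS
#' detections at or above the confidence threshold.
#'
#' @param detections Post-NMS detections data.frame.
#' @param confidence_thresh Score threshold (default 0.5).
#' @return Integer count.
#' @export
count_tpsn <- function(detections, confidence_thresh = 0.5) {
  det <- as_detections(detections)
  sum(det$score >= confidence_thresh)
}

#' Classical ellipse-based grain detector
#'
#' Backs the detector interface (image in, scored boxes out) with the
#' classical grain-analysis pipeline: threshold, extract regions, drop
#' impurities, and emit the bounding box of every region that passes the
#' single-grain ellipse gate as a score-1.0 detection. This lets the
#' end-to-end system run with no trained weights; any
#' `function(image) -> detections` can replace it.
#'
#' @param image Grayscale matrix.
#' @param config A [pipeline_config()].
#' @return Detections data.frame (`x0, y0, x1, y1, score, label`).
#' @export
detect_grains <- function(image, config = pipeline_config()) {
  res <- analyze_grains(image, config)
  iso <- Filter(function(r) r$category == "isolated", res$regions)
  if (!length(iso)) return(empty_detections())
  do.call(rbind, lapply(iso, function(r) {
    data.frame(
      x0 = r$bbox[1], y0 = r$bbox[2], x1 = r$bbox[3], y1 = r$bbox[4],
      score = 1.0, label = "grain", stringsAsFactors = FALSE
    )
  }))
}
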