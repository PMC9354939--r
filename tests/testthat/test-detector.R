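test_that("anchor counts and sizes follow the configuration", {
  cfg <- anchor_config()
  expect_equal(nrow(generate_anchors(cfg, 1, 1)), 9)
  expect_equal(nrow(generate_anchors(cfg, 10, 10)), 900)
  ## 32^2 at ratio 1:1 is a 32 x 32 box
  a <- generate_anchors(anchor_config(scales = 32^2, ratios = 1, stride = 16),
                        1, 1)
  expect_equal(unname(a[1, 3] - a[1, 1]), 32)
  expect_equal(unname(a[1, 4] - a[1, 2]), 32)
  ## centred on the cell centre
  expect_equal(unname((a[1, 1] + a[1, 3]) / 2), 8)
  ## anchor count is H * W * scales * ratios in general
  for (hw in list(c(2, 3), c(5, 1), c(4, 4))) {
    expect_equal(nrow(generate_anchors(cfg, hw[1], hw[2])),
                 hw[1] * hw[2] * 9)
  }
  ## aspect ratios: h/w matches the requested ratio after rounding
  a2 <- generate_anchors(anchor_config(scales = 64^2, ratios = 2, stride = 8),
                         1, 1)
  expect_equal(unname((a2[1, 4] - a2[1, 2]) / (a2[1, 3] - a2[1, 1])), 2,
               tolerance = 0.05)
})

test_that("IoU matches closed forms and is symmetric and bounded", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  set.seed(1)
  a <- random_boxes(100); b <- random_boxes(100)
  am <- as.matrix(a[, 1:4]); bm <- as.matrix(b[, 1:4])
  v1 <- box_iou(am, bm); v2 <- box_iou(bm, am)
  expect_equal(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 1))
  expect_equal(box_iou(am, am), rep(1, 100))
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
})

test_that("roi_align matches trivial closed forms", {
  fm <- matrix(3.5, 8, 8)
  out <- roi_align(fm, c(0.7, 1.3, 6.2, 7.9), c(3, 3), 2)
  expect_equal(out, matrix(3.5, 3, 3))
  ## integer-aligned roi, one centred sample per 1x1 bin reads the values
  fm2 <- matrix(as.numeric(1:16), 4, 4)
  out2 <- roi_align(fm2, c(1, 1, 3, 3), c(2, 2), 1)
  expect_equal(out2, fm2[2:3, 2:3])
  expect_error(roi_align(fm2, c(2, 2, 2, 3)), "degenerate")
  expect_error(roi_align(fm2, c(0, 0, 9, 2)), "extent")
})

test_that("roi_align equals the brute-force bilinear oracle", {
  set.seed(42)
  for (case in 1:200) {
    h <- sample(6:16, 1); w <- sample(6:16, 1)
    fm <- matrix(rnorm(h * w), h, w)
    x0 <- runif(1, 0, w - 2); y0 <- runif(1, 0, h - 2)
    roi <- c(x0, y0, runif(1, x0 + 1, w), runif(1, y0 + 1, h))
    oh <- sample(1:7, 1); ow <- sample(1:7, 1)
    s <- sample(1:3, 1)
    expect_equal(
      roi_align(fm, roi, c(oh, ow), s),
      oracle_roi_align(fm, roi, oh, ow, s),
      tolerance = 1e-6
    )
  }
})

test_that("SE gating has the closed-form zero-weight behaviour", {
  x <- array(runif(2 * 3 * 32), c(2, 3, 32))
  z <- se_attention(x, matrix(0, 2, 32), matrix(0, 32, 2))
  expect_equal(z$gates, rep(0.5, 32))
  expect_equal(z$output, x / 2)
  ## constant channels: average equals max
  xc <- array(7, c(4, 4, 2))
  expect_equal(apply(xc, 3, mean), apply(xc, 3, max))
})

test_that("SE attention matches a scalar per-channel oracle and is bounded", {
  set.seed(7)
  C <- 32
  x <- array(rnorm(5 * 4 * C), c(5, 4, C))
  wts <- se_init_weights(C, reduction = 16, seed = 3)
  z <- se_attention(x, wts$W1, wts$W2)
  ## naive oracle
  s <- numeric(C)
  for (c in seq_len(C)) s[c] <- mean(x[, , c]) + max(x[, , c])
  hid <- pmax(as.vector(wts$W1 %*% s), 0)
  gates <- 1 / (1 + exp(-as.vector(wts$W2 %*% hid)))
  expect_equal(z$gates, gates, tolerance = 1e-6)
  for (c in seq_len(C)) {
    expect_equal(z$output[, , c], x[, , c] * gates[c], tolerance = 1e-6)
    expect_true(all(abs(z$output[, , c]) <= abs(x[, , c]) + 1e-12))
  }
  expect_true(all(z$gates > 0 & z$gates < 1))
  ## concat merge doubles the squeeze length
  wts2 <- se_init_weights(C, merge = "concat", seed = 3)
  z2 <- se_attention(x, wts2$W1, wts2$W2, merge = "concat")
  expect_length(z2$gates, C)
})

test_that("NMS keeps the best of overlapping boxes and matches the oracle", {
  one <- data.frame(x0 = 0, y0 = 0, x1 = 2, y1 = 2, score = 0.7)
  expect_equal(nrow(nms(one, 0.5)), 1)
  two <- data.frame(x0 = c(0, 0), y0 = c(0, 0), x1 = c(2, 2), y1 = c(2, 2),
                    score = c(0.9, 0.8))
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  set.seed(11)
  for (rep in 1:20) {
    det <- random_boxes(50, extent = 60, max_side = 25)
    for (th in c(0.3, 0.5, 0.7)) {
      kept <- nms(det, th)
      ora <- oracle_nms(det, th)
      expect_equal(nrow(kept), nrow(ora))
      expect_equal(unname(as.matrix(kept[, c("x0", "y0", "x1", "y1")])),
                   unname(ora), tolerance = 1e-12)
    }
  }
})

test_that("TPSN counts detections at or above the confidence threshold", {
  expect_equal(count_tpsn(NULL), 0)
  det <- data.frame(x0 = c(0, 3, 6), y0 = 0, x1 = c(2, 5, 8), y1 = 2,
                    score = c(0.9, 0.6, 0.4))
  expect_equal(count_tpsn(det, 0.5), 2)
  expect_equal(count_tpsn(det, 0), 3)
})

test_that("the classical detector finds every grain on a sparse panicle-free scene", {
  sp <- scene_spec(frame_width = 768, frame_height = 768, n_frames = 1,
                   n_isolated = 9, n_clusters = 0, n_impurities = 2,
                   seed = 57)
  sc <- generate_grain_scene(sp)
  det <- detect_grains(sc$frames[[1]])
  expect_equal(nrow(det), 9)
  expect_true(all(det$score == 1))
  ## detections line up with ground-truth boxes
  m <- match_detections(det, sc$truth$grains[, c("x0", "y0", "x1", "y1")],
                        iou_min = 0.5)
  expect_equal(m$tp, 9)
})
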