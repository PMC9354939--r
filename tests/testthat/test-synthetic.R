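test_that("empty scene renders blank frames with zero totals", {
  sp <- small_spec(n_isolated = 0, n_impurities = 0, seed = 3)
  sc <- generate_grain_scene(sp)
  expect_length(sc$frames, 2)
  expect_equal(sc$truth$totals$n_grains, 0)
  expect_equal(sc$truth$totals$n_isolated, 0)
  expect_equal(sc$truth$totals$n_touching, 0)
  ## only background + noise: nothing above the binarization threshold
  comp <- stitch_frames(sc$frames)
  expect_false(any(binarize(comp, 100)))
})

test_that("totals follow the construction and clusters merge", {
  sp <- scene_spec(frame_width = 512, frame_height = 512, n_frames = 1,
                   n_isolated = 5, n_clusters = 1, cluster_sizes = 3,
                   n_impurities = 0, seed = 7)
  sc <- generate_grain_scene(sp)
  expect_equal(sc$truth$totals$n_grains, 8)
  expect_equal(sc$truth$totals$n_isolated, 5)
  expect_equal(sc$truth$totals$n_touching, 3)
  expect_equal(
    sc$truth$totals$n_grains,
    sc$truth$totals$n_isolated + sc$truth$totals$n_touching
  )
  ## the 3 cluster members form one connected component: 5 + 1 regions
  regions <- extract_regions(binarize(sc$frames[[1]], 100))
  expect_length(regions, 6)
})

test_that("scene generation is deterministic in the seed", {
  sp <- small_spec(n_isolated = 6, n_clusters = 1, cluster_sizes = 2,
                   n_impurities = 2, seed = 11)
  a <- generate_grain_scene(sp)
  b <- generate_grain_scene(sp)
  expect_identical(a, b)
  c <- generate_grain_scene(small_spec(
    n_isolated = 6, n_clusters = 1, cluster_sizes = 2,
    n_impurities = 2, seed = 12
  ))
  expect_false(identical(a$frames, c$frames))
})

test_that("ground-truth boxes are inside the composite and one per grain", {
  sp <- small_spec(n_isolated = 8, n_clusters = 2, cluster_sizes = c(2, 2),
                   n_impurities = 1, seed = 5)
  sc <- generate_grain_scene(sp)
  g <- sc$truth$grains
  expect_equal(nrow(g), sc$truth$totals$n_grains)
  h <- sp$frame_height * sp$n_frames
  expect_true(all(g$x0 >= 0 & g$y0 >= 0 & g$x1 <= sp$frame_width &
                    g$y1 <= h))
  expect_true(all(g$x1 > g$x0 & g$y1 > g$y0))
})

test_that("rendered foreground area tracks the analytic ellipse areas", {
  sp <- scene_spec(frame_width = 768, frame_height = 768, n_frames = 1,
                   n_isolated = 10, n_clusters = 0, n_impurities = 0,
                   noise_sigma = 5, seed = 21)
  sc <- generate_grain_scene(sp)
  mask <- binarize(sc$frames[[1]], 100)
  analytic <- with(sc$truth$grains, sum(pi * (major_px / 2) * (minor_px / 2)))
  expect_lt(abs(sum(mask) - analytic) / analytic, 0.05)
})

test_that("a grain straddling the frame seam splits and reassembles exactly", {
  ## Deterministic single-grain scene: render the same ellipse once on a
  ## tall canvas (oracle) and compare pixel sets with the stitched frames.
  h <- 128; w <- 128
  cx <- 60; cy <- 127.3; a <- 30; b <- 15; th <- 0.4
  oracle <- oracle_render_ellipse(2 * h, w, cx, cy, a, b, th)
  f1 <- oracle[1:h, ]; f2 <- oracle[(h + 1):(2 * h), ]
  expect_gt(sum(f1 > 0), 0)           # pixels in both frames
  expect_gt(sum(f2 > 0), 0)
  stitched <- stitch_frames(list(f1, f2))
  expect_identical(stitched, oracle)
  expect_equal(sum(stitched > 0), sum(oracle > 0))
})

test_that("infeasible packing raises an explicit error", {
  sp <- scene_spec(frame_width = 96, frame_height = 96, n_frames = 1,
                   n_isolated = 40, n_clusters = 0, n_impurities = 0,
                   seed = 1)
  expect_error(generate_grain_scene(sp), "infeasible packing")
})

test_that("scene spec validation rejects bad parameters", {
  expect_error(scene_spec(foreground_level = 20, background_level = 180),
               "foreground")
  expect_error(scene_spec(n_isolated = -1), "counts")
  expect_error(scene_spec(n_clusters = 1, cluster_sizes = 1), "at least 2")
  expect_error(scene_spec(grain_major_px = c(-5, 1)), "axis")
})

test_that("panicle scenes carry one in-image box per grain, deterministically", {
  sp <- scene_spec(frame_width = 512, frame_height = 256, n_frames = 2,
                   seed = 1)
  sc <- generate_panicle_scene(sp, n_grains = 12)
  expect_equal(nrow(sc$annotations), 12)
  h <- 512; w <- 512
  with(sc$annotations, {
    expect_true(all(x0 >= 0 & y0 >= 0 & x1 <= w & y1 <= h))
    expect_true(all(x1 > x0 & y1 > y0))
  })
  ## each box contains rendered foreground
  fg <- sc$image > 100
  for (i in seq_len(nrow(sc$annotations))) {
    bb <- as.numeric(sc$annotations[i, c("x0", "y0", "x1", "y1")])
    expect_true(any(fg[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3]]))
  }
  sc2 <- generate_panicle_scene(sp, n_grains = 12)
  expect_identical(sc, sc2)
  ## zero grains: rachis only, empty annotations
  sc0 <- generate_panicle_scene(sp, n_grains = 0)
  expect_equal(nrow(sc0$annotations), 0)
  expect_gt(sum(sc0$image > 100), 0)  # the rachis is rendered
})

test_that("frames round-trip through PNG files", {
  sp <- small_spec(seed = 2)
  sc <- generate_grain_scene(sp)
  dir <- withr::local_tempdir()
  paths <- write_frames(sc$frames, dir, scene = "t")
  expect_length(paths, 2)
  back <- read_frames(dir)
  expect_equal(back, sc$frames)
})
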