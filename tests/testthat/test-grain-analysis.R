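test_that("background subtraction clamps to [0, 255]", {
  img <- matrix(c(200, 30, 100, 0), 2, 2)
  bg <- matrix(50, 2, 2)
  out <- subtract_background(img, bg)
  expect_equal(out, matrix(c(150, 0, 50, 0), 2, 2))
  expect_equal(subtract_background(img, img), matrix(0, 2, 2))
  expect_equal(subtract_background(img, matrix(0, 2, 2)), img)
  expect_error(subtract_background(img, matrix(0, 3, 2)), "shapes differ")
})

test_that("binarization is a strict threshold", {
  img <- matrix(c(0, 10, 11, 255), 2, 2)
  expect_equal(sum(binarize(img, 10)), 2)
  expect_false(any(binarize(matrix(0, 4, 4), 10)))
  expect_equal(sum(binarize(img, 0)), 3)
  expect_error(binarize(img, 300), "threshold")
})

test_that("region extraction recovers areas, boxes and LWR", {
  mask <- matrix(FALSE, 40, 60)
  mask[5:10, 5:10] <- TRUE     # 6x6 square
  mask[20:29, 30:49] <- TRUE   # 10x20 rectangle
  regs <- extract_regions(mask)
  expect_length(regs, 2)
  areas <- sort(vapply(regs, function(r) r$area, numeric(1)))
  expect_equal(areas, c(36, 200))
  ## LWR of the rectangle: uniform moments give exactly 2
  rect <- regs[[which.max(vapply(regs, function(r) r$area, numeric(1)))]]
  expect_equal(rect$lwr, 2, tolerance = 0.01)  # discrete pixel moments
  expect_equal(rect$bbox, c(29, 19, 49, 29))
  expect_length(extract_regions(matrix(FALSE, 5, 5)), 0)
})

test_that("LWR of a rendered 2:1 ellipse is close to 2", {
  img <- oracle_render_ellipse(100, 100, 49.5, 49.5, 30, 15, 0.7)
  regs <- extract_regions(img > 0)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$lwr, 2, tolerance = 0.1)
})

test_that("impurity removal partitions regions exactly", {
  sp <- scene_spec(frame_width = 640, frame_height = 640, n_frames = 1,
                   n_isolated = 5, n_clusters = 0, n_impurities = 3,
                   seed = 13)
  sc <- generate_grain_scene(sp)
  regs <- extract_regions(binarize(sc$frames[[1]], 100))
  parts <- remove_impurities(regs)
  expect_length(parts$kept, 5)
  expect_length(parts$removed, 3)
  expect_equal(length(parts$kept) + length(parts$removed), length(regs))
  expect_true(all(vapply(parts$removed, function(r) r$category,
                         character(1)) == "impurity"))
  ## vacuous bounds keep everything
  all_kept <- remove_impurities(regs, 0, Inf, 1, Inf)
  expect_length(all_kept$kept, length(regs))
  expect_length(all_kept$removed, 0)
  expect_equal(remove_impurities(list()), list(kept = list(), removed = list()))
  expect_error(remove_impurities(regs, 10, 5, 1, 2), "area_min")
})

test_that("ellipse fit recovers analytic contours nearly perfectly", {
  t <- seq(0, 2 * pi, length.out = 91)[-91]
  for (th in c(0, 0.65, 2.1)) {
    x <- 80 + 30 * cos(t) * cos(th) - 15 * sin(t) * sin(th)
    y <- 70 + 30 * cos(t) * sin(th) + 15 * sin(t) * cos(th)
    f <- fit_ellipse(cbind(x, y))
    expect_false(is.null(f))
    expect_equal(f$major_axis, 60, tolerance = 0.02)
    expect_equal(f$minor_axis, 30, tolerance = 0.02)
    expect_gte(f$match_score, 990)
    expect_equal(f$center, c(80, 70), tolerance = 0.1)
  }
})

test_that("a merged two-grain blob fails the single-ellipse gate", {
  sp <- scene_spec(frame_width = 384, frame_height = 384, n_frames = 1,
                   n_isolated = 1, n_clusters = 1, cluster_sizes = 2,
                   n_impurities = 0, seed = 31)
  sc <- generate_grain_scene(sp)
  regs <- remove_impurities(
    extract_regions(binarize(sc$frames[[1]], 100))
  )$kept
  expect_length(regs, 2)
  cls <- classify_regions(regs)
  cats <- sort(vapply(cls, function(r) r$category, character(1)))
  expect_equal(cats, c("isolated", "touching"))
  ## the touching blob either fails the fit outright or scores below 800
  blob <- cls[[which(vapply(cls, function(r) r$category, character(1)) ==
                       "touching")]]
  if (!is.null(blob$fit)) expect_lt(blob$fit$match_score, 800)
})

test_that("short contours yield no fit", {
  expect_null(fit_ellipse(cbind(c(0, 1, 2, 3), c(0, 1, 0, 1))))
  ## collinear points cannot define an ellipse
  expect_null(fit_ellipse(cbind(1:20, 2 * (1:20))))
})

test_that("the match-score gate can be disabled or made unreachable", {
  sp <- small_spec(n_isolated = 4, seed = 19)
  sc <- generate_grain_scene(sp)
  regs <- remove_impurities(
    extract_regions(binarize(stitch_frames(sc$frames), 100))
  )$kept
  all_iso <- classify_regions(regs, min_score = 0)
  expect_true(all(vapply(all_iso, function(r) r$category,
                         character(1)) == "isolated"))
  none_iso <- classify_regions(regs, min_score = 1001)
  expect_true(all(vapply(none_iso, function(r) r$category,
                         character(1)) == "touching"))
})

test_that("spikelet counting follows the area-division rule", {
  mk <- function(area, cat) {
    structure(list(label = 1, area = area, category = cat),
              class = "grain_region")
  }
  regs <- c(
    lapply(rep(1000, 4), mk, cat = "isolated"),
    list(mk(3000, "touching"))
  )
  cr <- count_spikelets(regs)
  expect_equal(cr$isolated_count, 4)
  expect_equal(cr$touching_raw, 3.0)
  expect_equal(cr$touching_count, 3L)
  expect_equal(cr$total_count, 7L)
  expect_equal(cr$mean_isolated_area, 1000)
  ## no touching regions
  cr2 <- count_spikelets(lapply(rep(1400, 10), mk, cat = "isolated"))
  expect_equal(cr2$total_count, 10L)
  expect_equal(cr2$touching_count, 0L)
  ## rounding is half-up on the summed quotients
  regs3 <- c(lapply(rep(1000, 2), mk, cat = "isolated"),
             list(mk(1500, "touching"), mk(1000, "touching")))
  expect_equal(count_spikelets(regs3)$touching_count, 3L)  # 2.5 rounds up
  ## touching without isolated is an error
  expect_error(count_spikelets(list(mk(3000, "touching"))), "undefined")
})

test_that("grain shape matches analytic axes and is rotation invariant", {
  base <- NULL
  for (th in c(0, 37 * pi / 180, 1.9)) {
    img <- oracle_render_ellipse(130, 130, 64.3, 64.7, 30, 15, th)
    regs <- classify_regions(extract_regions(img > 0), min_score = 0)
    sh <- measure_grain_shape(regs[[1]], pixel_resolution = 100)
    expect_equal(sh$grain_length_px, 60, tolerance = 0.02)
    expect_equal(sh$grain_width_px, 30, tolerance = 0.02)
    ## px -> mm at 100 um/px
    expect_equal(sh$grain_length_mm, sh$grain_length_px / 10)
    if (is.null(base)) base <- sh
    expect_equal(sh$grain_length_px, base$grain_length_px, tolerance = 0.02)
    expect_equal(sh$grain_width_px, base$grain_width_px, tolerance = 0.02)
  }
  ## shape of a touching blob is undefined
  reg <- structure(list(category = "touching"), class = "grain_region")
  expect_error(measure_grain_shape(reg), "isolated")
})

test_that("adding an isolated grain raises the total by exactly one", {
  for (n in c(3, 7, 12)) {
    sp <- scene_spec(frame_width = 768, frame_height = 384, n_frames = 2,
                     n_isolated = n, n_clusters = 0, n_impurities = 2,
                     seed = 47)
    res <- analyze_grains(stitch_frames(generate_grain_scene(sp)$frames))
    expect_equal(res$count$total_count, n)
  }
})

test_that("the pipeline is deterministic for a fixed composite", {
  sp <- small_spec(n_isolated = 6, n_clusters = 1, cluster_sizes = 2,
                   n_impurities = 1, seed = 29)
  comp <- stitch_frames(generate_grain_scene(sp)$frames)
  a <- analyze_grains(comp)
  b <- analyze_grains(comp)
  expect_identical(a$count, b$count)
  expect_identical(a$shapes, b$shapes)
})
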