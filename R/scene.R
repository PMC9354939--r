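#' Specify a synthetic line-scan grain scene
#'
#' A `scene_spec` describes one pass of the conveyor imaging unit: frame
#' geometry, how many grains to place (isolated and in touching clusters),
#' small impurities, gray levels and sensor noise, plus the RNG seed that
#' makes the scene reproducible. Grains are bright ellipses on a dark
#' background; the nominal grain is 60 x 30 px at the instrument's
#' 100 micrometre pixel pitch.
#'
#' @param frame_width Frame width in pixels (the line-scan sensor width).
#' @param frame_height Height of each frame strip in pixels.
#' @param n_frames Number of consecutive frames in the pass.
#' @param n_isolated Number of isolated grains (no contact with any other
#'   object).
#' @param n_clusters Number of touching clusters.
#' @param cluster_sizes Integer vector of length `n_clusters`, each >= 2:
#'   grains per cluster.
#' @param n_impurities Number of small circular impurities, all with area
#'   below the grain-area filter's lower bound so impurity removal is exact
#'   by construction.
#' @param grain_major_px,grain_minor_px Length-2 vectors `c(mean, sd)` of the
#'   full major/minor axis in pixels.
#' @param foreground_level,background_level Gray levels (0-255) of grain
#'   pixels and background; the foreground must be brighter.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise in
#'   gray levels.
#' @param seed Integer seed for the scene's single RNG stream.
#'
#' @return An object of class `scene_spec`.
#' @seealso [generate_grain_scene()], [generate_panicle_scene()]
#' @export
scene_spec <- function(frame_width = 2048, frame_height = 512, n_frames = 2,
                       n_isolated = 12, n_clusters = 2,
                       cluster_sizes = rep(2L, n_clusters), n_impurities = 3,
                       grain_major_px = c(60, 4), grain_minor_px = c(30, 2),
                       foreground_level = 180, background_level = 20,
                       noise_sigma = 5, seed = 1L) {
  spec <- list(
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    n_frames = as.integer(n_frames),
    n_isolated = as.integer(n_isolated),
    n_clusters = as.integer(n_clusters),
    cluster_sizes = as.integer(cluster_sizes),
    n_impurities = as.integer(n_impurities),
    grain_major_px = as.numeric(grain_major_px),
    grain_minor_px = as.numeric(grain_minor_px),
    foreground_level = as.numeric(foreground_level),
    background_level = as.numeric(background_level),
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (frame_width < 1 || frame_height < 1 || n_frames < 1) {
      stopf("frame dimensions and n_frames must be positive")
    }
    if (n_isolated < 0 || n_clusters < 0 || n_impurities < 0) {
      stopf("object counts must be >= 0")
    }
    if (length(cluster_sizes) != n_clusters) {
      stopf("cluster_sizes must have length n_clusters")
    }
    if (n_clusters > 0 && any(cluster_sizes < 2)) {
      stopf("every cluster needs at least 2 grains")
    }
    if (length(grain_major_px) != 2 || length(grain_minor_px) != 2 ||
        grain_major_px[1] <= 0 || grain_minor_px[1] <= 0 ||
        grain_major_px[2] < 0 || grain_minor_px[2] < 0) {
      stopf("grain axis parameters must be c(mean > 0, sd >= 0)")
    }
    if (grain_major_px[1] < grain_minor_px[1]) {
      stopf("grain major axis mean must be >= minor axis mean")
    }
    if (foreground_level <= background_level) {
      stopf("foreground_level must exceed background_level")
    }
    if (foreground_level > 255 || background_level < 0) {
      stopf("gray levels must lie in [0, 255]")
    }
    if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  })
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Line-scan scene spec: %d frame(s) of %d x %d px\n",
    x$n_frames, x$frame_width, x$frame_height
  ))
  cat(sprintf(
    "  grains: %d isolated + %d cluster(s) (%s) + %d impurities\n",
    x$n_isolated, x$n_clusters,
    if (x$n_clusters) paste(x$cluster_sizes, collapse = ",") else "-",
    x$n_impurities
  ))
  cat(sprintf(
    "  grain %.0fx%.0f px, levels fg %g / bg %g, noise sd %g, seed %d\n",
    x$grain_major_px[1], x$grain_minor_px[1],
    x$foreground_level, x$background_level, x$noise_sigma, x$seed
  ))
  invisible(x)
}

## ---- ellipse rendering ----------------------------------------------------

## Draw a filled ellipse on `canvas` (matrix, [row = y, col = x]).  A pixel is
## foreground when its centre (0-based integer coordinates) lies inside the
## ellipse.  a, b are SEMI-axes; theta in radians, counter-clockwise from +x.
draw_ellipse <- function(canvas, cx, cy, a, b, theta, level) {
  h <- nrow(canvas); w <- ncol(canvas)
  hw <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  hh <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  xs <- max(0L, floor(cx - hw)):min(w - 1L, ceiling(cx + hw))
  ys <- max(0L, floor(cy - hh)):min(h - 1L, ceiling(cy + hh))
  if (!length(xs) || !length(ys)) return(canvas)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u * u + v * v) <= 1
  sub <- canvas[ys + 1L, xs + 1L, drop = FALSE]
  sub[inside] <- level
  canvas[ys + 1L, xs + 1L] <- sub
  canvas
}

draw_disc <- function(canvas, cx, cy, r, level) {
  draw_ellipse(canvas, cx, cy, r, r, 0, level)
}

## Tight half-open pixel box of a rotated ellipse (pixel-centre rendering).
ellipse_box <- function(cx, cy, a, b, theta) {
  hw <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  hh <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  c(ceiling(cx - hw), ceiling(cy - hh), floor(cx + hw) + 1, floor(cy + hh) + 1)
}

## ---- grain scene generation ----------------------------------------------

#' Generate a synthetic line-scan grain scene with exact ground truth
#'
#' Renders bright elliptical grains on a dark background across `n_frames`
#' consecutive line-scan frames, then cuts the composite canvas into frame
#' strips so that grains may straddle frame boundaries exactly as they do
#' when a conveyor is imaged continuously. Touching clusters are built by
#' placing grain centres 0.7-0.9 times the sum of the two semi-minor axes
#' apart, side by side, which guarantees the members merge into a single
#' connected component; isolated grains keep at least 3 px clearance from
#' every other object. Impurities are small discs whose area lies below the
#' grain-area filter's lower bound.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{frames}{list of `n_frames` integer matrices (8-bit gray).}
#'     \item{truth}{ground truth: `grains` (one row per grain: centre, semi
#'       axes, orientation, cluster id, tight box), `impurities`, and
#'       `totals` (`n_grains`, `n_isolated`, `n_touching`).}
#'   }
#'   Identical `spec` (including seed) gives bit-identical output.
#' @examples
#' sc <- generate_grain_scene(scene_spec(
#'   frame_width = 256, frame_height = 256,
#'   n_frames = 1, n_isolated = 3, n_clusters = 0, n_impurities = 1, seed = 7
#' ))
#' sc$truth$totals
#' @export
generate_grain_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    h <- spec$frame_height * spec$n_frames
    w <- spec$frame_width
    placed <- place_scene_objects(spec, w, h)
    canvas <- matrix(spec$background_level, nrow = h, ncol = w)
    g <- placed$grains
    if (nrow(g)) {
      for (i in seq_len(nrow(g))) {
        canvas <- draw_ellipse(
          canvas, g$cx[i], g$cy[i], g$a[i], g$b[i], g$theta[i],
          spec$foreground_level
        )
      }
    }
    im <- placed$impurities
    if (nrow(im)) {
      for (i in seq_len(nrow(im))) {
        canvas <- draw_disc(canvas, im$cx[i], im$cy[i], im$r[i],
                            spec$foreground_level)
      }
    }
    if (spec$noise_sigma > 0) {
      canvas <- canvas + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    canvas <- matrix(as.integer(round(clamp(canvas, 0, 255))), h, w)
    frames <- lapply(seq_len(spec$n_frames), function(k) {
      rows <- ((k - 1L) * spec$frame_height + 1L):(k * spec$frame_height)
      canvas[rows, , drop = FALSE]
    })
    truth <- build_ground_truth(placed, w, h)
    list(frames = frames, truth = truth)
  })
}

## Sample grain axes; axes are stored as SEMI-axes internally.
sample_axes <- function(spec, n) {
  a <- pmax(stats::rnorm(n, spec$grain_major_px[1], spec$grain_major_px[2]), 4) / 2
  b <- pmax(stats::rnorm(n, spec$grain_minor_px[1], spec$grain_minor_px[2]), 2) / 2
  b <- pmin(b, a)  # keep major >= minor even in the tails
  list(a = a, b = b)
}

## Rejection-sample all object positions.  Every placed entity carries a
## bounding radius; new entities must keep >= 3 px clearance from all of them.
place_scene_objects <- function(spec, w, h, max_tries = 400L) {
  grains <- data.frame(
    cx = numeric(0), cy = numeric(0), a = numeric(0), b = numeric(0),
    theta = numeric(0), cluster_id = integer(0)
  )
  impurities <- data.frame(
    cx = numeric(0), cy = numeric(0), r = numeric(0)
  )
  occ_x <- numeric(0); occ_y <- numeric(0); occ_r <- numeric(0)
  gap <- 3

  admit <- function(cx, cy, r) {
    if (cx - r < 1 || cy - r < 1 || cx + r > w - 2 || cy + r > h - 2) {
      return(FALSE)
    }
    if (!length(occ_x)) return(TRUE)
    all((cx - occ_x)^2 + (cy - occ_y)^2 >= (r + occ_r + gap)^2)
  }
  occupy <- function(cx, cy, r) {
    occ_x[length(occ_x) + 1L] <<- cx
    occ_y[length(occ_y) + 1L] <<- cy
    occ_r[length(occ_r) + 1L] <<- r
  }
  fail <- function(kind) {
    stopf(paste0(
      "infeasible packing: could not place %s after %d attempts; ",
      "reduce object counts or enlarge the frames"
    ), kind, max_tries)
  }

  ## Clusters first (largest footprint), then isolated grains, then
  ## impurities, to keep the packing feasible at high densities.
  for (ci in seq_len(spec$n_clusters)) {
    k <- spec$cluster_sizes[ci]
    ax <- sample_axes(spec, k)
    theta <- stats::runif(1, 0, pi)
    ## Side-by-side chain: successive centres offset along the shared
    ## minor-axis direction, like spikelets lying flank to flank.  The
    ## centre spacing guarantees adjacent members merge into one connected
    ## component while keeping their (unphysical) interpenetration minimal,
    ## and the union is a distinctly non-elliptic blob.
    rel <- matrix(0, k, 2)
    phi <- theta + pi / 2
    for (j in seq_len(k)[-1]) {
      d <- stats::runif(1, 0.7, 0.9) * (ax$b[j - 1L] + ax$b[j])
      rel[j, ] <- rel[j - 1L, ] + d * c(cos(phi), sin(phi))
    }
    rel <- sweep(rel, 2, colMeans(rel))
    crad <- max(sqrt(rowSums(rel^2)) + ax$a)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, crad + 1, w - crad - 2)
      cy <- stats::runif(1, crad + 1, h - crad - 2)
      if (admit(cx, cy, crad)) { ok <- TRUE; break }
    }
    if (!ok) fail(sprintf("cluster %d (size %d)", ci, k))
    occupy(cx, cy, crad)
    grains <- rbind(grains, data.frame(
      cx = cx + rel[, 1], cy = cy + rel[, 2],
      a = ax$a, b = ax$b,
      theta = rep(theta, k),
      cluster_id = ci
    ))
  }

  for (gi in seq_len(spec$n_isolated)) {
    ax <- sample_axes(spec, 1)
    theta <- stats::runif(1, 0, pi)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, ax$a + 1, w - ax$a - 2)
      cy <- stats::runif(1, ax$a + 1, h - ax$a - 2)
      if (admit(cx, cy, ax$a)) { ok <- TRUE; break }
    }
    if (!ok) fail("an isolated grain")
    occupy(cx, cy, ax$a)
    grains <- rbind(grains, data.frame(
      cx = cx, cy = cy, a = ax$a, b = ax$b, theta = theta,
      cluster_id = NA_integer_
    ))
  }

  for (ii in seq_len(spec$n_impurities)) {
    r <- stats::runif(1, 4, 7)   # area 50-154 px^2, below the 400 px^2 filter
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, r + 1, w - r - 2)
      cy <- stats::runif(1, r + 1, h - r - 2)
      if (admit(cx, cy, r)) { ok <- TRUE; break }
    }
    if (!ok) fail("an impurity")
    occupy(cx, cy, r)
    impurities <- rbind(impurities, data.frame(cx = cx, cy = cy, r = r))
  }

  list(grains = grains, impurities = impurities)
}

build_ground_truth <- function(placed, w, h) {
  g <- placed$grains
  boxes <- if (nrow(g)) {
    t(mapply(ellipse_box, g$cx, g$cy, g$a, g$b, g$theta))
  } else {
    matrix(numeric(0), 0, 4)
  }
  grains <- data.frame(
    id = seq_len(nrow(g)),
    cx = g$cx, cy = g$cy,
    major_px = 2 * g$a, minor_px = 2 * g$b,
    theta = g$theta, cluster_id = g$cluster_id
  )
  grains$x0 <- boxes[, 1]; grains$y0 <- boxes[, 2]
  grains$x1 <- boxes[, 3]; grains$y1 <- boxes[, 4]
  im <- placed$impurities
  impurities <- data.frame(
    cx = im$cx, cy = im$cy, radius = im$r, area = pi * im$r^2
  )
  n_touch <- sum(!is.na(grains$cluster_id))
  list(
    grains = grains,
    impurities = impurities,
    totals = list(
      n_grains = nrow(grains),
      n_isolated = nrow(grains) - n_touch,
      n_touching = n_touch
    )
  )
}

## ---- panicle scene --------------------------------------------------------

#' Generate a synthetic threshed-panicle scene with box annotations
#'
#' Renders a rachis (the panicle's central stalk) as a thick polyline with
#' `n_grains` residual spikelets attached alongside it, and returns one
#' axis-aligned ground-truth box per grain, ready to be written as PASCAL
#' VOC annotations. Slight overlaps between neighbouring spikelets are
#' allowed, as on a real threshed panicle.
#'
#' @param spec A [scene_spec()]; `frame_width` and
#'   `frame_height * n_frames` give the image size, grain axes and gray
#'   levels are reused, and `seed` drives the scene's RNG stream.
#' @param n_grains Number of residual spikelets to attach.
#' @param rachis Optional polyline as an n x 2 matrix of (x, y) vertices
#'   (0-based) inside the image; default is a gently bending vertical stalk
#'   down the image centre.
#' @return A list with `image` (integer matrix) and `annotations`
#'   (data.frame with half-open 0-based `x0, y0, x1, y1` and `label`).
#' @export
generate_panicle_scene <- function(spec, n_grains = 12, rachis = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  if (!is_count(n_grains)) stopf("n_grains must be a non-negative integer")
  w <- spec$frame_width
  h <- spec$frame_height * spec$n_frames
  with_seed(spec$seed, {
    if (is.null(rachis)) {
      ys <- seq(0.08 * h, 0.92 * h, length.out = 9)
      xs <- w / 2 + (w / 12) * sin(seq(0, pi, length.out = 9)) +
        stats::rnorm(9, 0, w / 80)
      rachis <- cbind(clamp(xs, 2, w - 3), ys)
    }
    if (!is.matrix(rachis) || ncol(rachis) != 2 || nrow(rachis) < 2) {
      stopf("rachis must be an n x 2 matrix with n >= 2")
    }
    if (any(rachis[, 1] < 0 | rachis[, 1] >= w |
              rachis[, 2] < 0 | rachis[, 2] >= h)) {
      stopf("rachis polyline must lie within the image")
    }
    canvas <- matrix(spec$background_level, nrow = h, ncol = w)
    canvas <- draw_polyline(canvas, rachis, width = 3,
                            level = spec$foreground_level)
    ann <- empty_detections()[, c("x0", "y0", "x1", "y1", "label")]
    if (n_grains > 0) {
      ## Arc-length positions along the rachis, one grain per slot with
      ## jitter, attached left/right alternately near the stalk.
      tpos <- (seq_len(n_grains) - stats::runif(n_grains, 0.1, 0.9)) / n_grains
      pts <- polyline_point(rachis, tpos)
      side <- ifelse(seq_len(n_grains) %% 2 == 0, 1, -1)
      ax <- sample_axes(spec, n_grains)
      rows <- vector("list", n_grains)
      for (i in seq_len(n_grains)) {
        ang <- pts$angle[i] + side[i] *
          (pi / 2 + stats::runif(1, -pi / 5, pi / 5))
        off <- ax$b[i] * stats::runif(1, 1.0, 1.8)
        cx <- clamp(pts$x[i] + off * cos(ang), ax$a[i] + 1, w - ax$a[i] - 2)
        cy <- clamp(pts$y[i] + off * sin(ang), ax$a[i] + 1, h - ax$a[i] - 2)
        theta <- ang + stats::runif(1, -pi / 10, pi / 10)
        canvas <- draw_ellipse(canvas, cx, cy, ax$a[i], ax$b[i], theta,
                               spec$foreground_level)
        bb <- ellipse_box(cx, cy, ax$a[i], ax$b[i], theta)
        rows[[i]] <- data.frame(
          x0 = bb[1], y0 = bb[2], x1 = bb[3], y1 = bb[4],
          label = "grain", stringsAsFactors = FALSE
        )
      }
      ann <- do.call(rbind, rows)
    }
    if (spec$noise_sigma > 0) {
      canvas <- canvas + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    canvas <- matrix(as.integer(round(clamp(canvas, 0, 255))), h, w)
    list(image = canvas, annotations = ann)
  })
}

## Point(s) at fractional arc length t in [0, 1] along a polyline, plus the
## local tangent angle.
polyline_point <- function(poly, t) {
  seg <- diff(poly)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- clamp(t, 0, 1) * total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- clamp(idx, 1, nrow(seg))
  frac <- (s - cum[idx]) / len[idx]
  list(
    x = poly[idx, 1] + frac * seg[idx, 1],
    y = poly[idx, 2] + frac * seg[idx, 2],
    angle = atan2(seg[idx, 2], seg[idx, 1])
  )
}

draw_polyline <- function(canvas, poly, width, level) {
  half <- width / 2
  for (i in seq_len(nrow(poly) - 1L)) {
    p <- poly[i, ]; q <- poly[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((q - p)^2))))
    for (t in seq(0, 1, length.out = n)) {
      canvas <- draw_disc(canvas, p[1] + t * (q[1] - p[1]),
                          p[2] + t * (q[2] - p[2]), half, level)
    }
  }
  canvas
}

## ---- file output ----------------------------------------------------------

#' Write / read scene frames as 8-bit grayscale PNG files
#'
#' Frames are written as `<scene>_<index>.png`; `read_frames` restores them
#' (sorted by name) as a list of integer matrices.
#'
#' @param frames List of integer matrices (gray 0-255).
#' @param dir Output directory (created if needed).
#' @param scene Scene name used as the filename prefix.
#' @return `write_frames` returns the file paths invisibly; `read_frames`
#'   returns a list of integer matrices.
#' @export
write_frames <- function(frames, dir, scene = "scene") {
  if (!length(frames)) stopf("no frames to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.png", scene, seq_along(frames)))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}

#' @rdname write_frames
#' @param paths Character vector of PNG paths, or a directory whose `*.png`
#'   files are read in name order.
#' @export
read_frames <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.png$", full.names = TRUE))
  }
  if (!length(paths)) stopf("no PNG frames found")
  lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- a[, , 1]   # tolerate RGB(A) input
    matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  })
}

#' Write ground truth as a plain CSV (one row per grain)
#'
#' @param truth Ground truth from [generate_grain_scene()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$grains, path, row.names = FALSE)
  invisible(path)
}
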