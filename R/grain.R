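## Grain image analysis pipeline: background subtraction -> fixed-threshold
## binarization -> connected regions -> impurity removal by area and
## length-width ratio -> ellipse-based isolated/touching classification ->
## area-ratio spikelet counting and grain shape measurement.

#' Subtract a background model from an image
#'
#' Enhances foreground contrast before thresholding. Output pixels are
#' `clamp(image - background, 0, 255)`.
#'
#' @param image,background 8-bit grayscale matrices of identical shape.
#' @return Matrix of the same shape.
#' @export
subtract_background <- function(image, background) {
  if (!is.matrix(image) || !is.matrix(background)) {
    stopf("image and background must be matrices")
  }
  if (!identical(dim(image), dim(background))) {
    stopf("image (%s) and background (%s) shapes differ",
          paste(dim(image), collapse = "x"),
          paste(dim(background), collapse = "x"))
  }
  clamp(image - background, 0, 255)
}

#' Binarize a grayscale image with a fixed threshold
#'
#' @param image Grayscale matrix.
#' @param threshold Gray level in `[0, 255]`; pixels strictly above it
#'   become foreground.
#' @return Logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(image, threshold) {
  if (!is_number(threshold) || threshold < 0 || threshold > 255) {
    stopf("threshold must be a single value in [0, 255]")
  }
  image > threshold
}

#' Extract connected foreground regions
#'
#' Labels the mask with 8-connectivity and computes, per region: pixel area,
#' tight half-open bounding box, the ordered outer contour (0-based x, y
#' pixel coordinates), the centroid, and the length-width ratio (LWR) of the
#' region's second-moment equivalent ellipse (major/minor, so LWR >= 1).
#'
#' @param mask Logical matrix from [binarize()].
#' @return List of region records (class `grain_region`), each with elements
#'   `label`, `area`, `bbox`, `contour`, `centroid`, `lwr`, `category`
#'   (initially `NA`).
#' @export
extract_regions <- function(mask) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) return(list())
  lab_img <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  labels <- t(EBImage::imageData(lab_img))
  contours <- EBImage::ocontour(lab_img)  # (x, y), 0-based, label order
  idx <- which(labels > 0)
  lab_of <- labels[idx]
  row0 <- (idx - 1L) %% nrow(labels)        # 0-based y
  col0 <- (idx - 1L) %/% nrow(labels)       # 0-based x
  xs <- split(col0, lab_of)
  ys <- split(row0, lab_of)
  n <- max(labels)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    x <- xs[[as.character(k)]]
    y <- ys[[as.character(k)]]
    area <- length(x)
    mx <- mean(x); my <- mean(y)
    ## Central second moments of the pixel set -> equivalent ellipse.
    cxx <- mean((x - mx)^2); cyy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    tr <- cxx + cyy
    det2 <- cxx * cyy - cxy^2
    disc <- sqrt(max(tr^2 / 4 - det2, 0))
    l1 <- tr / 2 + disc
    l2 <- tr / 2 - disc
    lwr <- if (l2 <= 1e-12) Inf else sqrt(l1 / l2)
    out[[k]] <- structure(
      list(
        label = k,
        area = area,
        bbox = c(min(x), min(y), max(x) + 1L, max(y) + 1L),
        contour = contours[[k]],
        pixels = cbind(x = x, y = y),
        centroid = c(mx, my),
        lwr = lwr,
        category = NA_character_
      ),
      class = "grain_region"
    )
  }
  out
}

#' @export
print.grain_region <- function(x, ...) {
  cat(sprintf(
    "Region %d: area %d px, bbox [%d,%d)x[%d,%d), LWR %.2f, category %s\n",
    x$label, x$area, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4], x$lwr,
    if (is.na(x$category)) "-" else x$category
  ))
  invisible(x)
}

#' Remove impurity regions by area and length-width ratio
#'
#' Partitions the regions: a region is kept when its area lies in
#' `[area_min, area_max]` and its LWR in `[lwr_min, lwr_max]`; everything
#' else (dust, broken fragments, elongated debris) is removed. Because the
#' isolated/touching split happens *after* this step, the default bounds
#' must admit merged touching blobs of several grains, not just one grain:
#' they bracket anything from a single grain (~1,400 px^2 at 100 um/px) up
#' to an aggregation of about eight, while sub-grain dust (area below
#' 400 px^2) and highly elongated debris are dropped.
#'
#' @param regions List from [extract_regions()].
#' @param area_min,area_max Area bounds in pixels.
#' @param lwr_min,lwr_max LWR bounds (dimensionless).
#' @return List with elements `kept` and `removed`; removed regions have
#'   `category = "impurity"`. The two lists partition the input exactly.
#' @export
remove_impurities <- function(regions, area_min = 400, area_max = 12000,
                              lwr_min = 1.0, lwr_max = 6.0) {
  if (area_min >= area_max) stopf("area_min must be < area_max")
  if (lwr_min >= lwr_max) stopf("lwr_min must be < lwr_max")
  keep <- vapply(regions, function(r) {
    r$area >= area_min && r$area <= area_max &&
      r$lwr >= lwr_min && r$lwr <= lwr_max
  }, logical(1))
  removed <- lapply(regions[!keep], function(r) {
    r$category <- "impurity"
    r
  })
  list(kept = regions[keep], removed = removed)
}

#' Fit an ellipse to a region contour and score the match
#'
#' Direct least-squares conic fitting (numerically stable partitioned
#' formulation) of the contour points, followed by a boundary agreement
#' score: the fitted ellipse is sampled at `n_samples` uniformly spaced
#' parameter angles and the score is 1000 times the fraction of samples
#' whose nearest contour point lies within `tol_px`. 1000 is a perfect
#' match; the isolated/touching gate is 800 by default. The fit is rejected
#' (`NULL`) when the contour has fewer than 5 points, is degenerate, or the
#' recovered axes fall outside the plausible single-grain ranges.
#'
#' @param contour n x 2 matrix of (x, y) contour coordinates.
#' @param minor_range,major_range Allowed full axis lengths in pixels,
#'   scaled from the nominal 30 x 60 px grain.
#' @param tol_px Boundary agreement tolerance in pixels.
#' @param n_samples Number of boundary sample points for the score.
#' @return A list (`center`, `major_axis`, `minor_axis`, `orientation`,
#'   `match_score`), or `NULL` for a rejected fit (set
#'   `options(grainscan.verbose = TRUE)` to have the reason messaged).
#' @export
fit_ellipse <- function(contour, minor_range = c(18, 45),
                        major_range = c(40, 90), tol_px = 2.0,
                        n_samples = 360L) {
  if (is.null(contour) || !is.matrix(contour) || nrow(contour) < 5L) {
    return(fit_failure("contour has fewer than 5 points"))
  }
  fit <- fit_conic_ellipse(contour[, 1], contour[, 2])
  if (is.null(fit)) {
    return(fit_failure("degenerate contour (no ellipse fit)"))
  }
  major <- 2 * fit$a
  minor <- 2 * fit$b
  if (!is.finite(major) || !is.finite(minor)) {
    return(fit_failure("non-finite axes from the conic fit"))
  }
  if (minor < minor_range[1] || minor > minor_range[2] ||
        major < major_range[1] || major > major_range[2]) {
    return(fit_failure(sprintf(
      "axes %.1f x %.1f px outside allowed single-grain ranges", major, minor
    )))
  }
  t <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  ex <- fit$cx + fit$a * cos(t) * cos(fit$theta) -
    fit$b * sin(t) * sin(fit$theta)
  ey <- fit$cy + fit$a * cos(t) * sin(fit$theta) +
    fit$b * sin(t) * cos(fit$theta)
  d2 <- outer(ex, contour[, 1], "-")^2 + outer(ey, contour[, 2], "-")^2
  nearest <- sqrt(apply(d2, 1, min))
  score <- 1000 * mean(nearest <= tol_px)
  list(
    center = c(fit$cx, fit$cy),
    major_axis = major,
    minor_axis = minor,
    orientation = fit$theta,
    match_score = score
  )
}

## Rejected fits return NULL; the reason is messaged only when
## options(grainscan.verbose = TRUE), so batch runs stay quiet.
fit_failure <- function(reason) {
  if (isTRUE(getOption("grainscan.verbose", FALSE))) {
    message("fit_ellipse: ", reason)
  }
  NULL
}

## Direct least-squares ellipse fit (Halir-Flusser partitioned scatter
## matrices). Returns centre, SEMI-axes a >= b and orientation, or NULL.
fit_conic_ellipse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) return(NULL)
  a1 <- vecs[, ok[1]]
  coef <- c(a1, as.vector(T1 %*% a1))   # A, B, C, D, E, F (centred frame)
  names(coef) <- c("A", "B", "C", "D", "E", "F")
  p <- conic_to_ellipse(coef)
  if (is.null(p)) return(NULL)
  p$cx <- p$cx + mx
  p$cy <- p$cy + my
  p
}

conic_to_ellipse <- function(k) {
  A <- k["A"]; B <- k["B"]; C <- k["C"]; D <- k["D"]; E <- k["E"]; F <- k["F"]
  den <- B^2 - 4 * A * C
  if (den >= -1e-14) return(NULL)        # not an ellipse
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  root <- sqrt((A - C)^2 + B^2)
  s1 <- num * ((A + C) + root)
  s2 <- num * ((A + C) - root)
  if (s1 <= 0 || s2 <= 0) return(NULL)
  ax1 <- -sqrt(s1) / den
  ax2 <- -sqrt(s2) / den
  theta <- if (abs(B) < 1e-12 && A <= C) 0 else atan2(-B, C - A) / 2
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  ## atan2 form gives the axis of ax1; swap orientation if ax2 is the major.
  if (ax2 > ax1) theta <- theta + pi / 2
  theta <- theta %% pi
  list(cx = unname(cx), cy = unname(cy), a = unname(a), b = unname(b),
       theta = unname(theta))
}

#' Classify regions as isolated or touching via the ellipse gate
#'
#' A region is *isolated* when a single-ellipse fit exists, its axes fall in
#' the allowed single-grain ranges, and its boundary match score reaches
#' `min_score`; otherwise it is *touching* (a merged blob of two or more
#' grains). Impurities are assumed removed upstream.
#'
#' @param regions List from [remove_impurities()]`$kept`.
#' @param fits Optional list of precomputed [fit_ellipse()] results, one per
#'   region; computed when omitted.
#' @param min_score Match score gate in `[0, 1000]` (1000 = perfect).
#' @param ... Passed on to [fit_ellipse()] when fits are computed here.
#' @return The regions, each with `category` set to `"isolated"` or
#'   `"touching"` and the fit stored as `$fit` (possibly `NULL`).
#' @export
classify_regions <- function(regions, fits = NULL, min_score = 800, ...) {
  if (is.null(fits)) {
    fits <- lapply(regions, function(r) fit_ellipse(r$contour, ...))
  }
  if (length(fits) != length(regions)) {
    stopf("need exactly one fit attempt per region")
  }
  Map(function(r, f) {
    isolated <- !is.null(f) && f$match_score >= min_score
    r$category <- if (isolated) "isolated" else "touching"
    r$fit <- f
    r
  }, regions, fits)
}

#' Count spikelets from classified regions
#'
#' The number of isolated regions is the isolated spikelet count. Each
#' touching region contributes its area divided by the mean isolated-grain
#' area; these quotients are summed over all touching regions and the sum is
#' rounded (half up) once, giving the touching spikelet count. The total is
#' the sum of the two.
#'
#' @param regions List of classified regions from [classify_regions()].
#' @return An object of class `count_result` with fields `isolated_count`,
#'   `touching_raw`, `touching_count`, `total_count`, `mean_isolated_area`.
#' @export
count_spikelets <- function(regions) {
  cats <- vapply(regions, function(r) r$category, character(1))
  if (anyNA(cats)) stopf("regions must be classified first")
  iso <- regions[cats == "isolated"]
  tou <- regions[cats == "touching"]
  if (length(tou) && !length(iso)) {
    stopf(paste0(
      "touching regions present but no isolated grains: ",
      "mean isolated area is undefined"
    ))
  }
  mean_area <- if (length(iso)) {
    mean(vapply(iso, function(r) r$area, numeric(1)))
  } else {
    NA_real_
  }
  touching_raw <- if (length(tou)) {
    sum(vapply(tou, function(r) r$area, numeric(1))) / mean_area
  } else {
    0
  }
  touching_count <- floor(touching_raw + 0.5)   # round half up, once
  structure(
    list(
      isolated_count = length(iso),
      touching_raw = touching_raw,
      touching_count = as.integer(touching_count),
      total_count = length(iso) + as.integer(touching_count),
      mean_isolated_area = mean_area
    ),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf(
    "Spikelet count: %d total (%d isolated + %d touching; raw %.2f, mean isolated area %.0f px)\n",
    x$total_count, x$isolated_count, x$touching_count, x$touching_raw,
    if (is.na(x$mean_isolated_area)) NA else x$mean_isolated_area
  ))
  invisible(x)
}

#' Measure grain length and width from a region contour
#'
#' Grain length (GL) is the Euclidean distance between the two farthest
#' contour points; grain width (GW) is the maximum perpendicular extent of
#' the contour about the GL chord, summing the largest excursions on the two
#' sides. To avoid the half-pixel quantisation bias of integer boundary
#' coordinates, the measurement contour is a sub-pixel iso-contour of the
#' region mask (marching squares at level 0.5) smoothed with a short
#' circular moving average; when the region does not carry its pixel set
#' the stored integer contour is used as a fallback. Millimetre values use
#' the instrument pixel pitch (`mm = px * pixel_resolution / 1000`).
#'
#' @param region A region record; must be classified `"isolated"` (the shape
#'   of a merged touching blob is undefined).
#' @param pixel_resolution Micrometres per pixel.
#' @return List with `grain_length_px`, `grain_width_px`, `grain_length_mm`,
#'   `grain_width_mm`.
#' @export
measure_grain_shape <- function(region, pixel_resolution = 100) {
  if (!identical(region$category, "isolated")) {
    stopf("grain shape is defined for isolated regions only")
  }
  pts <- subpixel_contour(region)
  if (is.null(pts)) pts <- region$contour
  if (is.null(pts) || nrow(pts) < 3L) stopf("contour needs >= 3 points")
  d <- as.matrix(stats::dist(pts))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  p <- pts[ij[1], ]; q <- pts[ij[2], ]
  gl <- d[ij[1], ij[2]]
  u <- (q - p) / gl
  nrm <- c(-u[2], u[1])
  s <- (pts[, 1] - p[1]) * nrm[1] + (pts[, 2] - p[2]) * nrm[2]
  gw <- max(s, 0) - min(s, 0)   # largest excursion on each side of the chord
  scale <- pixel_resolution / 1000
  list(
    grain_length_px = gl,
    grain_width_px = gw,
    grain_length_mm = gl * scale,
    grain_width_mm = gw * scale
  )
}

## Sub-pixel boundary of a region: marching squares at iso-level 0.5 on the
## region's own mask patch, followed by a 9-point circular moving average
## that suppresses the +/-0.5 px vertex jitter (whose extremes would
## otherwise bias the max-based GL/GW measures). Returns NULL when the
## region has no stored pixel set.
subpixel_contour <- function(region, k = 9L) {
  px <- region$pixels
  if (is.null(px) || nrow(px) < 4L) return(NULL)
  x0 <- min(px[, 1]); y0 <- min(px[, 2])
  w <- max(px[, 1]) - x0 + 1L
  h <- max(px[, 2]) - y0 + 1L
  patch <- matrix(0, h + 2L, w + 2L)   # 1-px pad so the contour closes
  patch[cbind(px[, 2] - y0 + 2L, px[, 1] - x0 + 2L)] <- 1
  cl <- grDevices::contourLines(
    x = seq_len(h + 2L) - 2L + y0,     # row (y) coordinates, 0-based
    y = seq_len(w + 2L) - 2L + x0,     # col (x) coordinates
    z = patch, levels = 0.5
  )
  if (!length(cl)) return(NULL)
  longest <- cl[[which.max(vapply(cl, function(p) length(p$x), numeric(1)))]]
  pts <- cbind(longest$y, longest$x)   # back to (x, y)
  n <- nrow(pts)
  if (n > 1L && all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) return(NULL)
  if (k > 1L && n > k) {
    h2 <- k %/% 2
    out <- pts
    for (j in 1:2) {
      v <- pts[, j]
      acc <- v
      for (s in seq_len(h2)) {
        acc <- acc + v[((seq_len(n) - 1L + s) %% n) + 1L] +
          v[((seq_len(n) - 1L - s) %% n) + 1L]
      }
      out[, j] <- acc / k
    }
    pts <- out
  }
  pts
}

#' Run the full grain image analysis pipeline on a composite image
#'
#' Convenience orchestration of [subtract_background()], [binarize()],
#' [extract_regions()], [remove_impurities()], [classify_regions()],
#' [count_spikelets()] and [measure_grain_shape()], driven by a
#' [pipeline_config()].
#'
#' @param composite Grayscale matrix (a stitched conveyor pass).
#' @param config A [pipeline_config()].
#' @param background Optional background model matrix; when supplied it is
#'   subtracted before thresholding.
#' @return List with `count` (a `count_result`), `regions` (classified kept
#'   regions), `removed` (impurities) and `shapes` (data.frame, one row per
#'   isolated grain).
#' @export
analyze_grains <- function(composite, config = pipeline_config(),
                           background = NULL) {
  img <- composite
  if (!is.null(background)) img <- subtract_background(img, background)
  mask <- binarize(img, config$threshold)
  regions <- extract_regions(mask)
  parts <- remove_impurities(regions, config$area_min, config$area_max,
                             config$lwr_min, config$lwr_max)
  classified <- classify_regions(
    parts$kept, min_score = config$min_score,
    minor_range = config$minor_range, major_range = config$major_range,
    tol_px = config$tol_px
  )
  count <- count_spikelets(classified)
  iso <- Filter(function(r) r$category == "isolated", classified)
  shapes <- if (length(iso)) {
    do.call(rbind, lapply(iso, function(r) {
      sh <- measure_grain_shape(r, config$pixel_resolution)
      data.frame(
        label = r$label, area = r$area,
        GL_px = sh$grain_length_px, GW_px = sh$grain_width_px,
        GL_mm = sh$grain_length_mm, GW_mm = sh$grain_width_mm
      )
    }))
  } else {
    data.frame(
      label = integer(0), area = integer(0),
      GL_px = numeric(0), GW_px = numeric(0),
      GL_mm = numeric(0), GW_mm = numeric(0)
    )
  }
  list(count = count, regions = classified, removed = parts$removed,
       shapes = shapes)
}
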