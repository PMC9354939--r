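#' Pipeline configuration
#'
#' Collects every tunable threshold of the grain pipeline, the detector
#' post-processing and the metrics in one validated object. All values are
#' documented with their defaults; unknown keys are rejected.
#'
#' @param threshold Fixed binarization gray level (0-255).
#' @param area_min,area_max Grain area bounds in px^2 for impurity removal.
#' @param lwr_min,lwr_max Length-width ratio bounds for impurity removal.
#' @param minor_range,major_range Allowed full ellipse axis ranges (px) for
#'   the single-grain gate, scaled from the nominal 30 x 60 px grain.
#' @param min_score Ellipse boundary match score gate (0-1000).
#' @param tol_px Boundary agreement tolerance in pixels.
#' @param pixel_resolution Micrometres per pixel.
#' @param confidence Detection confidence threshold for TPSN counting.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param iou_min IoU defining a positive detection in evaluation.
#' @param overlap_rows Rows shared between consecutive frame buffers.
#' @param seed Default RNG seed for simulation commands.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(threshold = 100,
                            area_min = 400, area_max = 12000,
                            lwr_min = 1.0, lwr_max = 6.0,
                            minor_range = c(18, 45),
                            major_range = c(40, 90),
                            min_score = 800, tol_px = 2.0,
                            pixel_resolution = 100,
                            confidence = 0.5, nms_iou = 0.5, iou_min = 0.5,
                            overlap_rows = 0L, seed = 1L) {
  cfg <- list(
    threshold = threshold, area_min = area_min, area_max = area_max,
    lwr_min = lwr_min, lwr_max = lwr_max,
    minor_range = as.numeric(minor_range),
    major_range = as.numeric(major_range),
    min_score = min_score, tol_px = tol_px,
    pixel_resolution = pixel_resolution,
    confidence = confidence, nms_iou = nms_iou, iou_min = iou_min,
    overlap_rows = as.integer(overlap_rows), seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (threshold < 0 || threshold > 255) stopf("threshold must be in [0, 255]")
    if (area_min >= area_max) stopf("area_min must be < area_max")
    if (lwr_min >= lwr_max) stopf("lwr_min must be < lwr_max")
    if (length(minor_range) != 2 || length(major_range) != 2 ||
          minor_range[1] >= minor_range[2] || major_range[1] >= major_range[2]) {
      stopf("axis ranges must be increasing length-2 vectors")
    }
    if (min_score < 0 || min_score > 1000) {
      stopf("min_score must be in [0, 1000]")
    }
    if (tol_px <= 0) stopf("tol_px must be > 0")
    if (pixel_resolution <= 0) stopf("pixel_resolution must be > 0")
    for (v in c(confidence, nms_iou, iou_min)) {
      if (v < 0 || v > 1) stopf("confidence and IoU thresholds must be in [0, 1]")
    }
    if (overlap_rows < 0) stopf("overlap_rows must be >= 0")
  })
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration as flat key = value text
#'
#' The on-disk schema is one `key = value` pair per line (`#` comments
#' allowed); multi-valued keys such as `minor_range` use comma-separated
#' values. Unknown keys are rejected on read.
#'
#' @param path Config file path.
#' @return `read_config` returns a validated [pipeline_config()];
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  known <- names(formals(pipeline_config))
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stopf("cannot parse config line: '%s'", ln)
    key <- trimws(kv[1])
    if (!key %in% known) {
      stopf("unknown config key '%s' (known: %s)", key,
            paste(known, collapse = ", "))
    }
    val <- suppressWarnings(as.numeric(strsplit(trimws(kv[2]), ",")[[1]]))
    if (anyNA(val)) stopf("non-numeric value for config key '%s'", key)
    args[[key]] <- val
  }
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(nm) {
    sprintf("%s = %s", nm, paste(config[[nm]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
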