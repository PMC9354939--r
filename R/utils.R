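## Shared internal helpers.
##
## Conventions used throughout the package:
##  * images are numeric/integer matrices with nrow = height (y, rows) and
##    ncol = width (x, columns), gray levels 0..255;
##  * coordinates are 0-based with the origin at the top-left pixel, x
##    running across columns and y down rows;
##  * boxes are half-open, c(x0, y0, x1, y1) with x0 <= x < x1.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards so scene generation never perturbs user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Validate a half-open box c(x0, y0, x1, y1).
check_box <- function(box, what = "box") {
  if (!is.numeric(box) || length(box) != 4L || anyNA(box)) {
    stopf("%s must be numeric c(x0, y0, x1, y1)", what)
  }
  if (box[3] <= box[1] || box[4] <= box[2]) {
    stopf("%s is degenerate: x1 > x0 and y1 > y0 required", what)
  }
  invisible(box)
}

box_area <- function(box) {
  (box[3] - box[1]) * (box[4] - box[2])
}

## Empty detections table, shared by the detector and metrics modules.
empty_detections <- function() {
  data.frame(
    x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
    score = numeric(0), label = character(0), stringsAsFactors = FALSE
  )
}

as_detections <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
        (is.list(x) && !is.data.frame(x) && !length(x))) {
    return(empty_detections())   # includes [] read back from JSON
  }
  if (!is.data.frame(x)) stopf("detections must be a data.frame")
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(x))) {
    stopf("detections need columns %s", paste(need, collapse = ", "))
  }
  if (is.null(x$score)) x$score <- rep(1, nrow(x))
  if (is.null(x$label)) x$label <- rep("grain", nrow(x))
  if (any(x$x1 <= x$x0) || any(x$y1 <= x$y0)) {
    stopf("detections contain degenerate boxes")
  }
  if (any(x$score < 0 | x$score > 1)) stopf("scores must lie in [0, 1]")
  x
}
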