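#' Build a frame sequence from line-scan frames
#'
#' A `frame_sequence` is an ordered set of 8-bit grayscale frame strips from
#' one conveyor pass. All frames must share the same width (the line-scan
#' sensor is a single fixed row of pixels); the default pixel pitch of
#' 100 micrometres matches a 2,048-pixel sensor imaging a 204.8 mm field of
#' view.
#'
#' @param frames List of integer/numeric matrices, identical width.
#' @param pixel_resolution Micrometres per pixel (> 0).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, pixel_resolution = 100) {
  if (!is.list(frames) || !length(frames)) {
    stopf("frames must be a non-empty list of matrices")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stopf("every frame must be a matrix")
  }
  widths <- vapply(frames, ncol, integer(1))
  if (length(unique(widths)) != 1L) {
    stopf("all frames must share one width; got widths %s",
          paste(unique(widths), collapse = ", "))
  }
  if (!is_number(pixel_resolution) || pixel_resolution <= 0) {
    stopf("pixel_resolution must be a positive number")
  }
  structure(
    list(frames = frames, pixel_resolution = pixel_resolution),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  hts <- vapply(x$frames, nrow, integer(1))
  cat(sprintf(
    "Frame sequence: %d frame(s), width %d px, heights %s, %g um/px\n",
    length(x$frames), ncol(x$frames[[1]]), paste(hts, collapse = "+"),
    x$pixel_resolution
  ))
  invisible(x)
}

#' Stitch consecutive line-scan frames into one composite image
#'
#' The line-scan camera images the conveyor continuously, so consecutive
#' frame strips abut exactly: the bottom row of frame *k* is spatially
#' adjacent to the top row of frame *k + 1*. Stitching therefore
#' concatenates the frames vertically in acquisition order, which makes any
#' foreground region cut by a frame boundary 8-connected with its
#' continuation in the next frame; connected-component analysis of the
#' composite then sees every grain whole. Pixel values are unchanged.
#'
#' @param seq A [frame_sequence()], or a plain list of equal-width matrices.
#' @param overlap_rows Rows shared between consecutive frame buffers
#'   (dropped from the top of each frame after the first). The instrument
#'   emits abutting frames, so the default is 0.
#' @return The composite matrix; its height is the sum of frame heights
#'   (minus any overlap).
#' @examples
#' f1 <- matrix(0L, 4, 8); f2 <- matrix(0L, 4, 8)
#' dim(stitch_frames(list(f1, f2)))  # 8 x 8
#' @export
stitch_frames <- function(seq, overlap_rows = 0L) {
  if (is.list(seq) && !inherits(seq, "frame_sequence")) {
    seq <- frame_sequence(seq)
  }
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is_count(overlap_rows)) stopf("overlap_rows must be a count >= 0")
  frames <- seq$frames
  if (overlap_rows > 0 && length(frames) > 1L) {
    frames <- c(frames[1], lapply(frames[-1], function(f) {
      if (nrow(f) <= overlap_rows) {
        stopf("overlap_rows (%d) must be smaller than every frame height",
              overlap_rows)
      }
      f[-seq_len(overlap_rows), , drop = FALSE]
    }))
  }
  do.call(rbind, frames)
}
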