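#' Frame sequences
#'
#' A `frame_sequence` is a time-ordered stack of 2-D ultrasound images with
#' acquisition metadata: pixel spacing (mm/px) and frame rate (Hz). Rows run
#' along the axial (depth) direction, increasing away from the transducer;
#' columns run laterally. Both the B-mode and CEUS channels of an acquisition
#' are stored as separate `frame_sequence` objects.
#'
#' @param frames numeric 3-D array `[rows, cols, n_frames]`, or a list of
#'   equally sized matrices.
#' @param pixel_spacing_mm pixel pitch, mm per pixel (isotropic).
#' @param frame_rate_hz acquisition frame rate in Hz.
#' @param channel optional label, e.g. `"ceus"` or `"bmode"`.
#' @return an object of class `frame_sequence`.
#' @examples
#' fs <- frame_sequence(array(0, c(8, 8, 3)), pixel_spacing_mm = 0.1,
#'                      frame_rate_hz = 114)
#' n_frames(fs)
#' @export
frame_sequence <- function(frames, pixel_spacing_mm, frame_rate_hz,
                           channel = NA_character_) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      abort("all frames must have identical dimensions (ragged stack)")
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    abort("pixel_spacing_mm must be a positive number")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    abort("frame_rate_hz must be a positive number")
  structure(
    list(frames = frames,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         frame_rate_hz = as.numeric(frame_rate_hz),
         channel = channel),
    class = "frame_sequence")
}

#' @rdname frame_sequence
#' @param x a `frame_sequence`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_sequence"))
  dim(x$frames)[3]
}

#' Extract one frame as a matrix
#' @param x a `frame_sequence`.
#' @param i frame index.
#' @return numeric matrix with a `spacing_mm` attribute.
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "frame_sequence"))
  m <- x$frames[, , i]
  attr(m, "spacing_mm") <- x$pixel_spacing_mm
  m
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_sequence> %s: %d x %d px, %d frames, %.4g mm/px, %.4g Hz\n",
    x$channel %||% "?", d[1], d[2], d[3], x$pixel_spacing_mm,
    x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)
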