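#' Calibrated grayscale image sequence
#'
#' A time-lapse stack: an ordered list of 2-D grayscale matrices (intensities
#' in `[0, 1]`, rows top-down as stored in image files) plus the physical
#' calibration shared by all frames.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param pixel_size um/px, > 0.
#' @param frame_interval min, > 0.
#' @return an `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size = 1, frame_interval = 1) {
  if (!is.list(frames) || length(frames) == 0)
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, TRUE)))
    stop("every frame must be a 2-D matrix", call. = FALSE)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("all frames must have the same shape", call. = FALSE)
  if (any(vapply(frames, function(f) any(!is.finite(f)), TRUE)))
    stop("frames contain non-finite values", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/px)", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 || !is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a single positive number (min)", call. = FALSE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %d frames of %d x %d px; %.4g um/px, %.4g min/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)
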