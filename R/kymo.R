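# Kymographs, tissue segmentation and edge tracking.

#' x-velocity kymograph
#'
#' Space-time heat map of horizontal velocity: u-values (um/min) are
#' averaged over the y axis and over all frames falling in each time bin of
#' `row_duration`, and binned along x in columns of `col_width`. Cells with
#' no valid vectors are `NA`. Defaults (10 min rows, 42 um columns) follow
#' the conventional display for electrotaxis monolayer data.
#'
#' @param fields list of [velocity_field()] objects from consecutive frame
#'   pairs (shared calibration).
#' @param row_duration time per kymograph row, min; must be at least one
#'   frame interval.
#' @param col_width spatial bin along x, um.
#' @return a `kymograph`: list with `values` (rows = time bins, cols = x
#'   bins), `row_duration`, `col_width`, `row_times` (bin start, min),
#'   `col_centers` (um), `quantity = "x_velocity"`.
#' @export
xvelocity_kymograph <- function(fields, row_duration = 10, col_width = 42) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  if (length(fields) < 1) stop("need at least one field", call. = FALSE)
  dt <- fields[[1]]$frame_interval
  if (row_duration < dt)
    stop("'row_duration' must be at least one frame interval", call. = FALSE)
  if (col_width <= 0) stop("'col_width' must be > 0", call. = FALSE)
  n <- length(fields)
  tstart <- (seq_len(n) - 1) * dt
  rows <- floor(tstart / row_duration) + 1L
  nrows <- max(rows)
  xmax <- max(vapply(fields, function(f) max(f$x) * f$pixel_size, 0))
  ncols <- max(1L, ceiling(xmax / col_width))
  ssum <- matrix(0, nrows, ncols)
  cnt <- matrix(0, nrows, ncols)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    vel <- field_velocities(f)
    x_um <- f$x * f$pixel_size
    ci <- pmin(pmax(floor(x_um / col_width) + 1L, 1L), ncols)
    for (j in seq_along(ci)) {
      ok <- f$valid[, j]
      if (any(ok)) {
        ssum[rows[k], ci[j]] <- ssum[rows[k], ci[j]] + sum(vel$u[ok, j])
        cnt[rows[k], ci[j]] <- cnt[rows[k], ci[j]] + sum(ok)
      }
    }
  }
  vals <- ssum / cnt
  vals[cnt == 0] <- NA_real_
  structure(list(values = vals, row_duration = row_duration,
                 col_width = col_width,
                 row_times = (seq_len(nrows) - 1) * row_duration,
                 col_centers = (seq_len(ncols) - 0.5) * col_width,
                 quantity = "x_velocity"),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %s: %d rows x %d cols (%.3g min/row, %.3g um/col)\n",
              x$quantity, nrow(x$values), ncol(x$values), x$row_duration,
              x$col_width))
  invisible(x)
}

#' Segment tissue from background by local texture
#'
#' Phase-contrast tissue is texture-rich while free substrate is smooth, so
#' the tissue mask is obtained by thresholding a local standard-deviation
#' map (box window of `texture_window` px), keeping the largest connected
#' component and filling holes. The threshold is Otsu's by default, floored
#' at `min_texture_sd` so that pure-noise frames are not segmented; a fixed
#' threshold can be supplied for synthetic images.
#'
#' @param frame numeric matrix (intensities, ideally in `[0, 1]`).
#' @param texture_window odd box size for the local SD, px.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param fixed_value SD threshold when `threshold = "fixed"`.
#' @param min_texture_sd absolute floor on the SD threshold; frames whose
#'   texture never exceeds it give an empty mask with a warning.
#' @return logical matrix, `TRUE` = tissue.
#' @export
segment_tissue <- function(frame, texture_window = 7,
                           threshold = c("otsu", "fixed"),
                           fixed_value = NULL, min_texture_sd = 0.05) {
  threshold <- match.arg(threshold)
  frame <- as.matrix(frame)
  if (min(dim(frame)) <= texture_window)
    stop("frame must be larger than 'texture_window'", call. = FALSE)
  k <- matrix(1 / texture_window^2, texture_window, texture_window)
  m1 <- EBImage::filter2(frame, k, boundary = "replicate")
  m2 <- EBImage::filter2(frame^2, k, boundary = "replicate")
  sdmap <- sqrt(pmax(m2 - m1^2, 0))
  above <- sdmap >= min_texture_sd
  if (mean(above) < 0.005) {
    warning("no texture above 'min_texture_sd'; returning empty mask",
            call. = FALSE)
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  if (mean(above) > 0.98) return(matrix(TRUE, nrow(frame), ncol(frame)))
  thr <- if (threshold == "fixed") {
    if (is.null(fixed_value)) stop("'fixed_value' required", call. = FALSE)
    fixed_value
  } else {
    mx <- max(sdmap)
    max(EBImage::otsu(EBImage::Image(sdmap / mx)) * mx, min_texture_sd)
  }
  mask <- sdmap >= thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  if (max(labm) >= 1) {
    sizes <- tabulate(labm[labm > 0])
    mask <- labm == which.max(sizes)
    mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  }
  matrix(as.logical(mask), nrow(frame), ncol(frame))
}

# Classed signal for frames on which an edge cannot be defined.
undefined_edge <- function(msg) {
  stop(structure(
    class = c("collmigr_undefined_edge", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Edge position of a tissue mask
#'
#' For each image row containing tissue, takes the x of the rightmost
#' (`leading`) or leftmost (`trailing`) tissue pixel and summarizes with
#' the median over rows (robust to fingers and streamers). Positions are
#' measured from the left frame edge: a mask filling columns `1..k` has
#' leading edge at `k` px and trailing edge at `0` px. Converted to um.
#'
#' @param mask logical matrix, `TRUE` = tissue.
#' @param side `"leading"` (right boundary) or `"trailing"` (left boundary).
#' @param pixel_size um/px.
#' @return edge position, um.
#' @export
edge_positions <- function(mask, side = c("leading", "trailing"),
                           pixel_size = 1) {
  side <- match.arg(side)
  mask <- as.matrix(mask)
  rows_with <- which(rowSums(mask) > 0)
  if (length(rows_with) == 0)
    undefined_edge("empty mask: edge position undefined")
  per_row <- vapply(rows_with, function(r) {
    cols <- which(mask[r, ])
    if (side == "leading") max(cols) else min(cols) - 1
  }, 0)
  stats::median(per_row) * pixel_size
}

#' Leading/trailing edge displacement over a movie
#'
#' Segments every frame, extracts both edge positions, and reports
#' displacement relative to the first frame. Negative leading-edge
#' displacement encodes retraction. Frames on which segmentation fails
#' yield missing entries, not errors.
#'
#' @param seq an [image_sequence()] with >= 2 frames.
#' @param texture_window,threshold,fixed_value,min_texture_sd passed to
#'   [segment_tissue()].
#' @return an `edge_trace` data frame: `time` (min), `leading_x`,
#'   `trailing_x` (um), `leading_disp`, `trailing_disp` (um, relative to
#'   frame 1).
#' @export
edge_displacement_series <- function(seq, texture_window = 7,
                                     threshold = c("otsu", "fixed"),
                                     fixed_value = NULL,
                                     min_texture_sd = 0.05) {
  stopifnot(inherits(seq, "image_sequence"))
  threshold <- match.arg(threshold)
  n <- length(seq$frames)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  lead <- trail <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    res <- tryCatch({
      m <- suppressWarnings(
        segment_tissue(seq$frames[[t]], texture_window, threshold,
                       fixed_value, min_texture_sd))
      c(edge_positions(m, "leading", seq$pixel_size),
        edge_positions(m, "trailing", seq$pixel_size))
    }, collmigr_undefined_edge = function(e) c(NA_real_, NA_real_))
    lead[t] <- res[1]; trail[t] <- res[2]
  }
  if (is.na(lead[1]))
    warning("edge undefined on the first frame; displacements are relative ",
            "to the first defined frame", call. = FALSE)
  ref_l <- lead[which(!is.na(lead))[1]]
  ref_t <- trail[which(!is.na(trail))[1]]
  structure(data.frame(
    time = (seq_len(n) - 1) * seq$frame_interval,
    leading_x = lead, trailing_x = trail,
    leading_disp = lead - ref_l, trailing_disp = trail - ref_t
  ), class = c("edge_trace", "data.frame"))
}

#' Wound-closure rate between two facing tissues
#'
#' The gap is the distance between the right tissue's left (trailing)
#' boundary and the left tissue's right (leading) boundary; the closure
#' rate is minus the slope of a least-squares line fit to gap(t). The
#' closure time is the first time at which the gap reaches zero, if any.
#'
#' @param left_tissue,right_tissue `edge_trace` objects on the same time
#'   base (the tissue left / right of the wound).
#' @return list with `rate_um_min`, `closure_time_min` (`NA` if the gap
#'   never closes) and `gap` (data frame of time, gap in um).
#' @export
wound_closure_rate <- function(left_tissue, right_tissue) {
  stopifnot(inherits(left_tissue, "edge_trace"),
            inherits(right_tissue, "edge_trace"))
  if (!isTRUE(all.equal(left_tissue$time, right_tissue$time)))
    stop("edge traces must share the same time base", call. = FALSE)
  gap <- right_tissue$trailing_x - left_tissue$leading_x
  ok <- !is.na(gap)
  if (sum(ok) < 2) stop("not enough defined gap values", call. = FALSE)
  if (gap[which(ok)[1]] <= 0)
    stop("initial gap must be positive", call. = FALSE)
  fit <- stats::lm(gap[ok] ~ left_tissue$time[ok])
  closed <- which(ok & gap <= 0)
  list(rate_um_min = -unname(stats::coef(fit)[2]),
       closure_time_min = if (length(closed)) left_tissue$time[closed[1]] else NA_real_,
       gap = data.frame(time = left_tissue$time, gap = gap))
}
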