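#' Gridded velocity field
#'
#' The central container of the package: one frame's velocity vectors on a
#' regular grid, as produced by PIV on an image pair or by binning simulated
#' agent displacements. Components are stored in px/frame together with the
#' physical calibration; [field_velocities()] exposes them in um/min.
#'
#' Sign convention is physical: `+u` is rightward motion (+x, toward the
#' cathode in an electrotaxis experiment) and `+v` is upward motion. Image
#' arrays are row-major top-down, so PIV negates the row lag when filling `v`.
#'
#' @param u,v numeric matrices (rows = y grid nodes, cols = x grid nodes) of
#'   velocity components. Interpreted according to `units`.
#' @param x,y numeric vectors of grid-node center coordinates in px
#'   (`length(x) == ncol(u)`, `length(y) == nrow(u)`). Defaults to unit
#'   spacing.
#' @param valid logical matrix marking trustworthy nodes; invalid nodes are
#'   excluded from every downstream metric. Defaults to all finite nodes.
#' @param snr optional numeric matrix of correlation signal-to-noise ratios.
#' @param pixel_size physical pixel size, um/px (> 0).
#' @param frame_interval time between frames, min (> 0).
#' @param units units of the supplied `u`, `v`: `"px_frame"` (storage unit)
#'   or `"um_min"` (converted on construction).
#'
#' @return An object of class `velocity_field`.
#' @seealso [field_velocities()], [compute_piv()], [trajectory_to_field()]
#' @export
velocity_field <- function(u, v, x = NULL, y = NULL, valid = NULL, snr = NULL,
                           pixel_size = 1, frame_interval = 1,
                           units = c("px_frame", "um_min")) {
  units <- match.arg(units)
  u <- as.matrix(u); v <- as.matrix(v)
  if (!identical(dim(u), dim(v)))
    stop("'u' and 'v' must have identical dimensions", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/px)", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 || !is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a single positive number (min)", call. = FALSE)
  if (is.null(x)) x <- seq_len(ncol(u))
  if (is.null(y)) y <- seq_len(nrow(u))
  if (length(x) != ncol(u) || length(y) != nrow(u))
    stop("grid coordinates do not match matrix dimensions", call. = FALSE)
  .check_regular(x, "x"); .check_regular(y, "y")
  if (units == "um_min") {
    u <- u * frame_interval / pixel_size
    v <- v * frame_interval / pixel_size
  }
  if (is.null(valid)) valid <- is.finite(u) & is.finite(v)
  valid <- as.matrix(valid)
  if (!is.logical(valid) || !identical(dim(valid), dim(u)))
    stop("'valid' must be a logical matrix matching 'u'", call. = FALSE)
  valid <- valid & is.finite(u) & is.finite(v)
  if (!is.null(snr)) {
    snr <- as.matrix(snr)
    if (!identical(dim(snr), dim(u)))
      stop("'snr' must match the grid dimensions", call. = FALSE)
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y), u = u, v = v, valid = valid,
         snr = snr, pixel_size = pixel_size, frame_interval = frame_interval),
    class = "velocity_field"
  )
}

.check_regular <- function(g, name) {
  if (length(g) > 1) {
    d <- diff(g)
    if (any(abs(d - d[1]) > 1e-6 * max(abs(d[1]), 1)))
      stop(sprintf("grid '%s' must be regularly spaced", name), call. = FALSE)
  }
  invisible(NULL)
}

#' Velocity components in physical units
#'
#' @param field a [velocity_field()].
#' @return list with matrices `u` and `v` in um/min
#'   (`px/frame * pixel_size / frame_interval`, exact).
#' @export
field_velocities <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  s <- field$pixel_size / field$frame_interval
  list(u = field$u * s, v = field$v * s)
}

# Valid, nonzero-magnitude vectors in um/min as a two-column matrix.
# Vectors with magnitude <= min_speed are dropped: the order parameters
# normalize by the magnitude and are undefined for stationary vectors.
.valid_vectors <- function(field, min_speed = 1e-9, drop_zero = TRUE) {
  vel <- field_velocities(field)
  keep <- field$valid
  if (drop_zero) keep <- keep & sqrt(vel$u^2 + vel$v^2) > min_speed
  cbind(u = vel$u[keep], v = vel$v[keep])
}

# Signal that a metric is undefined for this input (e.g. no valid vectors).
# A classed condition so callers can distinguish it from programming errors;
# metric_timeseries() converts it to a missing value.
undefined_metric <- function(msg) {
  stop(structure(
    class = c("collmigr_undefined_metric", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d grid, %d/%d valid nodes\n",
              nrow(x$u), ncol(x$u), sum(x$valid), length(x$valid)))
  cat(sprintf("  calibration: %.4g um/px, %.4g min/frame\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}
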