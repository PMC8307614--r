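#' Directionality of a velocity field
#'
#' Mean cosine of the angle between each velocity vector and the horizontal
#' x axis, `(1/N) * sum(cos(theta_i))` with `cos(theta_i) = u_i / |v_i|`,
#' taken over the valid, nonzero-magnitude vectors. The value lies in
#' `[-1, 1]`: `+1` means every vector points along +x (perfectly parallel to
#' a horizontal field, i.e. toward the cathode), `-1` perfectly antiparallel,
#' and `0` motion with no net horizontal preference.
#'
#' @param field a [velocity_field()].
#' @param min_speed magnitude threshold (um/min) below which vectors are
#'   treated as stationary and excluded (the cosine is undefined at zero
#'   magnitude).
#' @return a number in `[-1, 1]`.
#' @export
directionality <- function(field, min_speed = 1e-9) {
  m <- .valid_vectors(field, min_speed)
  if (nrow(m) == 0)
    undefined_metric("directionality undefined: no valid nonzero vectors")
  mean(m[, "u"] / sqrt(m[, "u"]^2 + m[, "v"]^2))
}

#' Coordination (polarization order parameter)
#'
#' Magnitude of the mean unit velocity vector,
#' `| (1/N) * sum(v_i / |v_i|) |`, over the valid nonzero vectors. This is
#' the polarization order parameter of collective-motion theory: 1 indicates
#' perfectly coordinated (aligned) motion across the tissue regardless of
#' the common direction, 0 wholly isotropic motion. Magnitudes do not enter:
#' the metric measures alignment only.
#'
#' @inheritParams directionality
#' @return a number in `[0, 1]`.
#' @export
coordination <- function(field, min_speed = 1e-9) {
  m <- .valid_vectors(field, min_speed)
  if (nrow(m) == 0)
    undefined_metric("coordination undefined: no valid nonzero vectors")
  mag <- sqrt(m[, "u"]^2 + m[, "v"]^2)
  sqrt(mean(m[, "u"] / mag)^2 + mean(m[, "v"] / mag)^2)
}

#' Mean migration speed
#'
#' Mean vector magnitude over valid nodes, in um/min. Zero vectors count:
#' speed is well defined for stationary regions.
#'
#' @inheritParams directionality
#' @return mean speed, um/min.
#' @export
mean_speed <- function(field) {
  m <- .valid_vectors(field, drop_zero = FALSE)
  if (nrow(m) == 0) undefined_metric("mean_speed undefined: no valid vectors")
  mean(sqrt(m[, "u"]^2 + m[, "v"]^2))
}

#' Mean x-velocity
#'
#' Mean of the horizontal component u over valid nodes, in um/min. The sign
#' carries direction: positive values indicate net motion along +x (toward
#' the cathode under horizontal stimulation).
#'
#' @inheritParams directionality
#' @return mean u, um/min.
#' @export
mean_x_velocity <- function(field) {
  m <- .valid_vectors(field, drop_zero = FALSE)
  if (nrow(m) == 0) undefined_metric("mean_x_velocity undefined: no valid vectors")
  mean(m[, "u"])
}

#' Neighbor velocity correlation
#'
#' For each valid grid node, the cosine similarity between the node's vector
#' and the mean vector of its valid 4-connected grid neighbors; the metric is
#' the mean over nodes that have at least one valid neighbor (and a nonzero
#' vector and neighbor mean). Values near 1 indicate that cells move like
#' their neighbors, near 0 no local correlation, near -1 locally antiparallel
#' motion.
#'
#' The estimator (4-connected neighbors, cosine to the neighbor mean) is a
#' declared choice; other neighbor-correlation estimators exist.
#'
#' @inheritParams directionality
#' @return a number in `[-1, 1]`.
#' @export
neighbor_correlation <- function(field, min_speed = 1e-9) {
  vel <- field_velocities(field)
  u <- vel$u; v <- vel$v; valid <- field$valid
  nr <- nrow(u); nc <- ncol(u)
  if (sum(valid) < 2)
    undefined_metric("neighbor_correlation undefined: fewer than 2 valid vectors")
  pad <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  su <- matrix(0, nr, nc); sv <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    vmask <- pad(valid * 1, d[1], d[2])
    su <- su + pad(u * valid, d[1], d[2])
    sv <- sv + pad(v * valid, d[1], d[2])
    cnt <- cnt + vmask
  }
  ok <- valid & cnt > 0
  if (!any(ok))
    undefined_metric("neighbor_correlation undefined: no valid neighbor pairs")
  mu <- su[ok] / cnt[ok]; mv <- sv[ok] / cnt[ok]
  u0 <- u[ok]; v0 <- v[ok]
  n0 <- sqrt(u0^2 + v0^2); nm <- sqrt(mu^2 + mv^2)
  keep <- n0 > min_speed & nm > min_speed
  if (!any(keep))
    undefined_metric("neighbor_correlation undefined: all node or neighbor means are zero")
  mean((u0[keep] * mu[keep] + v0[keep] * mv[keep]) / (n0[keep] * nm[keep]))
}

#' Polar distribution of velocity angles
#'
#' Pools `atan2(v, u)` over all valid nonzero vectors of one or more fields
#' and bins the angles into `n_bins` equal bins over `(-pi, pi]`, normalized
#' to fractions. Angle 0 is the +x direction (the field axis under
#' horizontal stimulation), so a stimulated, well-controlled tissue shows a
#' peak at 0.
#'
#' @param fields a [velocity_field()] or list of them.
#' @param n_bins number of angular bins (>= 2).
#' @inheritParams directionality
#' @return object of class `polar_histogram`: list with `bin_edges`
#'   (length `n_bins + 1`, radians) and `frequency` (fractions summing to 1).
#' @export
angle_distribution <- function(fields, n_bins = 24, min_speed = 1e-9) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2 || n_bins != round(n_bins))
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  vecs <- do.call(rbind, lapply(fields, .valid_vectors, min_speed = min_speed))
  if (is.null(vecs) || nrow(vecs) == 0)
    undefined_metric("angle_distribution undefined: no valid nonzero vectors")
  theta <- atan2(vecs[, "v"], vecs[, "u"])
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  # bins are left-open right-closed (a, b]; atan2 returns values in (-pi, pi]
  idx <- ceiling((theta + pi) / (2 * pi) * n_bins)
  idx[idx < 1] <- 1; idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, frequency = counts / sum(counts)),
            class = "polar_histogram")
}

#' @export
print.polar_histogram <- function(x, ...) {
  cat(sprintf("<polar_histogram> %d bins over (-pi, pi]; peak bin at %.2f rad (%.3f)\n",
              length(x$frequency),
              mean(x$bin_edges[which.max(x$frequency) + 0:1]),
              max(x$frequency)))
  invisible(x)
}

#' Per-frame metric time series
#'
#' Applies the scalar metrics (mean speed, mean x-velocity, directionality,
#' coordination, neighbor correlation) to each field of a movie and
#' optionally smooths each series with a centered moving average. Frames on
#' which a metric is undefined (no valid vectors) are carried as `NA`, never
#' as zero, and are skipped inside smoothing windows.
#'
#' @param fields list of [velocity_field()] objects, one per frame pair,
#'   assumed consecutive with the common `frame_interval`.
#' @param smoothing_window centered moving-average width in frames (odd;
#'   1 disables smoothing). Default 3.
#' @inheritParams directionality
#' @return a `metric_series` data frame with columns `time` (min, start of
#'   each frame pair), `speed`, `x_velocity`, `directionality`,
#'   `coordination`, `neighbor_correlation`, `n_valid`.
#' @export
metric_timeseries <- function(fields, smoothing_window = 3, min_speed = 1e-9) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  if (length(fields) < 1) stop("need at least one field", call. = FALSE)
  if (smoothing_window < 1 || smoothing_window != round(smoothing_window))
    stop("'smoothing_window' must be a positive integer", call. = FALSE)
  safe <- function(expr) tryCatch(expr, collmigr_undefined_metric = function(e) NA_real_)
  n <- length(fields)
  dt <- fields[[1]]$frame_interval
  out <- data.frame(
    time = (seq_len(n) - 1) * dt,
    speed = vapply(fields, function(f) safe(mean_speed(f)), 0),
    x_velocity = vapply(fields, function(f) safe(mean_x_velocity(f)), 0),
    directionality = vapply(fields, function(f) safe(directionality(f, min_speed)), 0),
    coordination = vapply(fields, function(f) safe(coordination(f, min_speed)), 0),
    neighbor_correlation = vapply(fields, function(f) safe(neighbor_correlation(f, min_speed)), 0),
    n_valid = vapply(fields, function(f) sum(f$valid), 0)
  )
  if (smoothing_window > 1) {
    for (col in c("speed", "x_velocity", "directionality", "coordination",
                  "neighbor_correlation"))
      out[[col]] <- .moving_average(out[[col]], smoothing_window)
  }
  structure(out, class = c("metric_series", "data.frame"),
            smoothing_window = smoothing_window)
}

# Centered moving average, NA-aware: each output is the mean of the
# available values in the window; all-NA windows stay NA.
.moving_average <- function(x, w) {
  h <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, 0)
}

#' Maximum migration speed of a series
#'
#' Maximum over frames of the (smoothed) spatial mean speed, the summary
#' used to report peak tissue response to stimulation.
#'
#' @param series a `metric_series` from [metric_timeseries()].
#' @return maximum smoothed mean speed, um/min.
#' @export
max_migration_speed <- function(series) {
  stopifnot(inherits(series, "metric_series"))
  if (all(is.na(series$speed)))
    undefined_metric("max_migration_speed undefined: all frames missing")
  max(series$speed, na.rm = TRUE)
}

#' Metric value at a given time
#'
#' Value of one metric column at the frame whose time is nearest `time_min`;
#' used e.g. to report directionality 4 h into stimulation.
#'
#' @param series a `metric_series`.
#' @param time_min target time in minutes.
#' @param metric column name, default `"directionality"`.
#' @return the metric value at the nearest frame (possibly `NA`).
#' @export
metric_at_time <- function(series, time_min, metric = "directionality") {
  stopifnot(inherits(series, "metric_series"), metric %in% names(series))
  series[[metric]][which.min(abs(series$time - time_min))]
}
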