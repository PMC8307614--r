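# File I/O: TIFF stacks with sidecar calibration, CSV interchange for
# velocity fields, trajectories, metric series, kymographs and edge traces.
# CSV is used for all interchange because it is inspectable and
# language-neutral; calibration travels in a sidecar JSON because TIFF tag
# conventions vary.

.fields_csv_cols <- c("frame", "grid_ix", "grid_iy", "x_um", "y_um",
                      "u_um_min", "v_um_min", "valid", "snr",
                      "pixel_size_um", "frame_interval_min")

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page 8/16-bit grayscale TIFF. Calibration is
#' taken from arguments or, if both are `NULL`, from a sidecar JSON file
#' `<path>.json` with fields `pixel_size_um` and `frame_interval_min`.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration overrides (um/px, min).
#' @return an [image_sequence()].
#' @export
read_image_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("input not readable: ", path, call. = FALSE)
  if (is.null(pixel_size) || is.null(frame_interval)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("calibration missing: supply pixel_size and frame_interval or a ",
           "sidecar JSON ", sidecar, call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_min
    if (is.null(pixel_size) || is.null(frame_interval))
      stop("sidecar JSON must define pixel_size_um and frame_interval_min",
           call. = FALSE)
  }
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop("cannot parse TIFF '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (length(dim(f)) == 3) {
      if (dim(f)[3] == 1) f <- f[, , 1]
      else stop("frame ", i, " is not grayscale", call. = FALSE)
    }
    if (any(!is.finite(f)))
      stop("frame ", i, " contains non-finite values", call. = FALSE)
    f
  })
  image_sequence(frames, pixel_size = pixel_size,
                 frame_interval = frame_interval)
}

#' Write a grayscale TIFF stack with sidecar calibration
#'
#' Intensities are clipped to `[0, 1]`; calibration is written to
#' `<path>.json`.
#'
#' @param seq an [image_sequence()].
#' @param path output TIFF path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(seq, path, bits_per_sample = 16) {
  stopifnot(inherits(seq, "image_sequence"))
  frames <- lapply(seq$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  jsonlite::write_json(
    list(pixel_size_um = seq$pixel_size,
         frame_interval_min = seq$frame_interval),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a velocity-field list as CSV
#'
#' One row per grid node per frame, with columns `frame`, `grid_ix`,
#' `grid_iy`, `x_um`, `y_um`, `u_um_min`, `v_um_min`, `valid`, `snr`,
#' `pixel_size_um`, `frame_interval_min`. Invalid nodes are written with
#' empty velocity values.
#'
#' @param fields a [velocity_field()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fields <- function(fields, path) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  tabs <- lapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    vel <- field_velocities(f)
    nx <- length(f$x); ny <- length(f$y)
    data.frame(
      frame = k,
      grid_ix = rep(seq_len(nx), each = ny),
      grid_iy = rep(seq_len(ny), nx),
      x_um = rep(f$x, each = ny) * f$pixel_size,
      y_um = rep(f$y, nx) * f$pixel_size,
      u_um_min = as.vector(ifelse(f$valid, vel$u, NA_real_)),
      v_um_min = as.vector(ifelse(f$valid, vel$v, NA_real_)),
      valid = as.integer(f$valid),
      snr = if (is.null(f$snr)) NA_real_ else as.vector(f$snr),
      pixel_size_um = f$pixel_size,
      frame_interval_min = f$frame_interval
    )
  })
  df <- do.call(rbind, tabs)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a velocity-field list from CSV
#'
#' Inverse of [write_fields()]. Unknown columns are ignored with a warning;
#' missing required columns or non-finite velocity values on valid nodes
#' are errors.
#'
#' @param path CSV path.
#' @return list of [velocity_field()] objects.
#' @export
read_fields <- function(path) {
  if (!file.exists(path)) stop("input not readable: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  extra <- setdiff(names(df), .fields_csv_cols)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  need <- setdiff(.fields_csv_cols, c("snr"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fields CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$frame), function(fr) {
    nx <- max(fr$grid_ix); ny <- max(fr$grid_iy)
    px <- fr$pixel_size_um[1]; dt <- fr$frame_interval_min[1]
    u <- matrix(NA_real_, ny, nx); v <- matrix(NA_real_, ny, nx)
    valid <- matrix(FALSE, ny, nx); snr <- matrix(NA_real_, ny, nx)
    idx <- cbind(fr$grid_iy, fr$grid_ix)
    u[idx] <- fr$u_um_min; v[idx] <- fr$v_um_min
    valid[idx] <- fr$valid == 1
    if ("snr" %in% names(fr)) snr[idx] <- fr$snr
    if (any(valid & (!is.finite(u) | !is.finite(v))))
      stop("fields CSV has non-finite velocities on valid nodes (frame ",
           fr$frame[1], ")", call. = FALSE)
    x <- sort(unique(fr$x_um)) / px
    y <- sort(unique(fr$y_um)) / px
    velocity_field(u, v, x = x, y = y, valid = valid, snr = snr,
                   pixel_size = px, frame_interval = dt, units = "um_min")
  })
}

#' Write / read an agent trajectory as CSV
#'
#' Columns: `frame`, `agent_id`, `x_um`, `y_um`, `heading_rad`,
#' `speed_um_min`.
#'
#' @param traj an `agent_trajectory`.
#' @param path CSV path.
#' @return `path` invisibly (write); a data frame (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "agent_trajectory"))
  Tn <- nrow(traj$x); n <- ncol(traj$x)
  df <- data.frame(
    frame = rep(seq_len(Tn), n),
    agent_id = rep(seq_len(n), each = Tn),
    x_um = as.vector(traj$x), y_um = as.vector(traj$y),
    heading_rad = as.vector(traj$heading),
    speed_um_min = as.vector(traj$speed)
  )
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("input not readable: ", path, call. = FALSE)
  utils::read.csv(path)
}

# Generic small-table writer used by the pipeline (deterministic output).
write_table_csv <- function(df, path) {
  utils::write.csv(format(as.data.frame(df), digits = 15, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
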