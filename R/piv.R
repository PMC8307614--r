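#' PIV parameters
#'
#' Defaults: a 32-px window with 50% overlap which, at a study-like
#' calibration of ~1.3 um/px, corresponds to interrogation squares of
#' roughly 42 um of monolayer; a three-point Gaussian subpixel estimator
#' (lowest peak-locking of the standard estimators, with parabolic as an
#' option); a signal-to-noise gate of 1.3 and a normalized-median outlier
#' threshold of 2 (standard PIV hygiene values).
#'
#' @param window_size interrogation window side, px; a power of two >= 8.
#' @param overlap window overlap fraction in `[0, 0.75]`.
#' @param subpixel `"gaussian3pt"` or `"parabolic"` peak refinement.
#' @param outlier_threshold normalized-median test threshold (> 0).
#' @param min_signal_to_noise minimum ratio of primary to secondary
#'   correlation peak (>= 1); nodes below are marked invalid.
#' @param correlation `"linear"` (zero-padded correlation with each lag
#'   normalized by its overlap area; unbiased for general texture, the
#'   default) or `"circular"` (classic unpadded FFT correlation; exact for
#'   texture that is periodic at the window size, slightly biased toward
#'   zero otherwise).
#' @return a `piv_params` list.
#' @export
piv_params <- function(window_size = 32, overlap = 0.5,
                       subpixel = c("gaussian3pt", "parabolic"),
                       outlier_threshold = 2, min_signal_to_noise = 1.3,
                       correlation = c("linear", "circular")) {
  subpixel <- match.arg(subpixel)
  correlation <- match.arg(correlation)
  if (window_size < 8 || bitwAnd(as.integer(window_size), as.integer(window_size) - 1L) != 0)
    stop("'window_size' must be a power of two >= 8", call. = FALSE)
  if (overlap < 0 || overlap > 0.75)
    stop("'overlap' must lie in [0, 0.75]", call. = FALSE)
  if (outlier_threshold <= 0)
    stop("'outlier_threshold' must be > 0", call. = FALSE)
  if (min_signal_to_noise < 1)
    stop("'min_signal_to_noise' must be >= 1", call. = FALSE)
  structure(list(window_size = as.integer(window_size), overlap = overlap,
                 subpixel = subpixel, outlier_threshold = outlier_threshold,
                 min_signal_to_noise = min_signal_to_noise,
                 correlation = correlation),
            class = "piv_params")
}

# Three-point subpixel refinement along one axis of the correlation plane.
# Gaussian fit requires positive samples; falls back to parabolic.
.subpixel_delta <- function(cm, c0, cp, method) {
  if (method == "gaussian3pt" && cm > 0 && c0 > 0 && cp > 0) {
    den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
    if (abs(den) > .Machine$double.eps) {
      d <- (log(cm) - log(cp)) / den
      if (is.finite(d) && abs(d) <= 1) return(d)
    }
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (abs(den) > .Machine$double.eps) {
    d <- (cm - cp) / den
    if (is.finite(d) && abs(d) <= 1) return(d)
  }
  0
}

#' PIV on one image pair
#'
#' Windowed FFT cross-correlation: for each interrogation window (spacing
#' `window_size * (1 - overlap)`), both windows are mean-subtracted and
#' circularly cross-correlated via FFT; the correlation maximum gives the
#' integer displacement, refined per axis by a three-point fit. Nodes whose
#' peak-to-second-peak ratio (second peak searched outside a 3-px exclusion
#' zone around the primary) falls below `min_signal_to_noise`, and windows
#' of zero variance, are marked invalid rather than raising an error.
#'
#' Sign convention: `+u` = rightward (+x) motion; `+v` = upward motion in
#' physical coordinates, i.e. the row-axis lag negated.
#'
#' @param frame_a,frame_b numeric matrices of the same shape (intensities).
#' @param params a [piv_params()].
#' @param pixel_size um/px calibration stored on the result.
#' @param frame_interval min/frame calibration stored on the result.
#' @return a [velocity_field()] (u, v stored in px/frame) with an `snr`
#'   matrix.
#' @export
compute_piv <- function(frame_a, frame_b, params = piv_params(),
                        pixel_size = 1, frame_interval = 1) {
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have identical shape", call. = FALSE)
  ws <- params$window_size
  if (nrow(frame_a) < ws || ncol(frame_a) < ws)
    stop("frames must be at least window_size in both axes", call. = FALSE)
  step <- max(1L, as.integer(round(ws * (1 - params$overlap))))
  r0 <- seq(1L, nrow(frame_a) - ws + 1L, by = step)
  c0 <- seq(1L, ncol(frame_a) - ws + 1L, by = step)
  # Default mode: zero-padded (linear) correlation, each lag normalized by
  # its overlap area, avoiding the triangular bias that pulls unnormalized
  # correlation peaks toward zero displacement. Circular mode skips the
  # padding and normalization. Search is limited to |lag| <= ws/4 (the
  # usual one-quarter rule), which also keeps the overlap normalization
  # well conditioned.
  circular <- params$correlation == "circular"
  np <- if (circular) ws else 2L * ws
  maxlag <- ws %/% 4L
  lags <- -maxlag:maxlag
  sel <- ((lags %% np) + 1L)  # index into the unshifted correlation plane
  norm2d <- if (circular) matrix(ws^2, length(lags), length(lags))
            else outer(ws - abs(lags), ws - abs(lags))
  ld <- outer(lags, rep(0L, length(lags)), "+")   # row-lag value per cell
  cd <- outer(rep(0L, length(lags)), lags, "+")   # col-lag value per cell
  u <- matrix(NA_real_, length(r0), length(c0))
  v <- matrix(NA_real_, length(r0), length(c0))
  snr <- matrix(NA_real_, length(r0), length(c0))
  valid <- matrix(FALSE, length(r0), length(c0))
  Ap <- matrix(0, np, np); Bp <- matrix(0, np, np)
  for (i in seq_along(r0)) for (j in seq_along(c0)) {
    A <- frame_a[r0[i]:(r0[i] + ws - 1L), c0[j]:(c0[j] + ws - 1L)]
    B <- frame_b[r0[i]:(r0[i] + ws - 1L), c0[j]:(c0[j] + ws - 1L)]
    A <- A - mean(A); B <- B - mean(B)
    if (sum(A * A) < .Machine$double.eps || sum(B * B) < .Machine$double.eps)
      next  # zero-variance window: invalid node, not an error
    if (circular) { Ap <- A; Bp <- B } else { Ap[1:ws, 1:ws] <- A; Bp[1:ws, 1:ws] <- B }
    Cfull <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp),
                           inverse = TRUE)) / np^2
    C <- Cfull[sel, sel] / norm2d
    pk <- which.max(C)
    nl <- length(lags)
    pr <- ((pk - 1L) %% nl) + 1L
    pc <- ((pk - 1L) %/% nl) + 1L
    peak <- C[pr, pc]
    # secondary peak outside a 3-px exclusion zone around the primary
    excl <- abs(ld - lags[pr]) <= 3 & abs(cd - lags[pc]) <= 3
    second <- suppressWarnings(max(C[!excl]))
    s <- if (!is.finite(second) || second <= 0) Inf else peak / second
    snr[i, j] <- s
    if (s < params$min_signal_to_noise) next
    dr <- lags[pr]; dc <- lags[pc]
    if (pr > 1L && pr < nl)
      dr <- dr + .subpixel_delta(C[pr - 1L, pc], peak, C[pr + 1L, pc],
                                 params$subpixel)
    if (pc > 1L && pc < nl)
      dc <- dc + .subpixel_delta(C[pr, pc - 1L], peak, C[pr, pc + 1L],
                                 params$subpixel)
    u[i, j] <- dc
    v[i, j] <- -dr  # image rows grow downward; physical +y is up
    valid[i, j] <- TRUE
  }
  velocity_field(u, v,
                 x = c0 + (ws - 1) / 2, y = r0 + (ws - 1) / 2,
                 valid = valid, snr = snr,
                 pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Normalized median test for vector outliers
#'
#' For each valid node, computes the residual of its vector to the median
#' vector of its valid 8-neighborhood, normalized by the median absolute
#' residual of those neighbors plus 0.1 px; nodes whose normalized residual
#' exceeds `outlier_threshold` are invalidated. No replacement or
#' interpolation is performed: downstream metrics simply see fewer valid
#' vectors. Fields with fewer than 9 valid nodes are returned unchanged
#' with a warning.
#'
#' @param field a [velocity_field()].
#' @param params a [piv_params()] (only `outlier_threshold` is used).
#' @return the field with outliers invalidated.
#' @export
filter_outliers <- function(field, params = piv_params()) {
  stopifnot(inherits(field, "velocity_field"))
  if (sum(field$valid) < 9) {
    warning("fewer than 9 valid vectors; outlier filter skipped", call. = FALSE)
    return(field)
  }
  u <- field$u; v <- field$v; valid <- field$valid
  nr <- nrow(u); nc <- ncol(u)
  bad <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j]) next
    ri <- max(1, i - 1):min(nr, i + 1)
    cj <- max(1, j - 1):min(nc, j + 1)
    nb <- valid[ri, cj]
    nb[ri == i, cj == j] <- FALSE
    if (!any(nb)) next
    un <- u[ri, cj][nb]; vn <- v[ri, cj][nb]
    mu <- stats::median(un); mv <- stats::median(vn)
    res_nb <- sqrt((un - mu)^2 + (vn - mv)^2)
    rm_ <- stats::median(res_nb)
    res0 <- sqrt((u[i, j] - mu)^2 + (v[i, j] - mv)^2)
    if (res0 / (rm_ + 0.1) > params$outlier_threshold) bad[i, j] <- TRUE
  }
  field$valid <- valid & !bad
  field
}

#' PIV over a whole movie
#'
#' Runs [compute_piv()] followed by [filter_outliers()] on each successive
#' frame pair. Failures on individual pairs are recorded as warnings and
#' yield an all-invalid field, not an error.
#'
#' @param seq an [image_sequence()] with at least 2 frames.
#' @param params a [piv_params()].
#' @param filter apply the outlier filter (default TRUE).
#' @return list of `length(seq) - 1` [velocity_field()] objects.
#' @export
piv_movie <- function(seq, params = piv_params(), filter = TRUE) {
  stopifnot(inherits(seq, "image_sequence"))
  n <- length(seq$frames)
  if (n < 2) stop("need at least 2 frames for PIV", call. = FALSE)
  lapply(seq_len(n - 1), function(t) {
    f <- compute_piv(seq$frames[[t]], seq$frames[[t + 1]], params,
                     pixel_size = seq$pixel_size,
                     frame_interval = seq$frame_interval)
    if (filter) f <- filter_outliers(f, params)
    f
  })
}
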