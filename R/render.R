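# Synthetic image rendering: speckle textures with a known displacement
# field (ground truth for PIV) and moving-edge tissue scenarios (ground
# truth for segmentation and edge tracking).

# Periodic speckle texture: Gaussian blobs on a torus, normalized to [0, 1].
# Periodicity makes integer shifts exact circular shifts, which downstream
# shift-theorem checks rely on.
.speckle_texture <- function(shape, density, radius) {
  h <- shape[1]; w <- shape[2]
  n <- max(1, round(density * h * w))
  r <- floor(runif(n, 0, h)) + 1
  c <- floor(runif(n, 0, w)) + 1
  amp <- runif(n, 0.5, 1)
  img <- matrix(0, h, w)
  idx <- (c - 1) * h + r
  s <- rowsum(amp, idx)
  img[as.integer(rownames(s))] <- s
  dr <- 0:(h - 1); dr <- pmin(dr, h - dr)
  dc <- 0:(w - 1); dc <- pmin(dc, w - dc)
  G <- exp(-outer(dr^2, dc^2, "+") / (2 * radius^2))
  out <- Re(stats::fft(stats::fft(img) * stats::fft(G), inverse = TRUE)) / (h * w)
  rng <- range(out)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, h, w))
  (out - rng[1]) / diff(rng)
}

# Periodic bilinear sampling of img at fractional (row, col) coordinate
# matrices R, C (same shape as img).
.sample_periodic <- function(img, R, C) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  wrap <- function(i, n) ((i - 1) %% n) + 1
  i00 <- cbind(as.vector(wrap(r0, h)), as.vector(wrap(c0, w)))
  i10 <- cbind(as.vector(wrap(r0 + 1, h)), as.vector(wrap(c0, w)))
  i01 <- cbind(as.vector(wrap(r0, h)), as.vector(wrap(c0 + 1, w)))
  i11 <- cbind(as.vector(wrap(r0 + 1, h)), as.vector(wrap(c0 + 1, w)))
  fr <- as.vector(fr); fc <- as.vector(fc)
  out <- img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
  matrix(out, h, w)
}

#' Render a speckle movie with a known displacement field
#'
#' Generates a random Gaussian-blob speckle texture (a stand-in for
#' phase-contrast cell texture) and advects it by a prescribed per-pixel
#' displacement: frame `t+1` is frame `t` warped by the field with periodic
#' bilinear interpolation. The displacement convention matches the PIV
#' output convention: `u` is motion along +x (columns, rightward), `v`
#' along physical +y (upward, i.e. toward smaller row indices).
#'
#' @param displacement either a length-2 numeric `(u, v)` in px/frame for a
#'   uniform field, or a list with matrices `u` and `v` of dimension
#'   `shape`.
#' @param shape `c(rows, cols)` of the frames, px.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed for the texture.
#' @param speckle_density expected blobs per pixel (default 0.02).
#' @param speckle_radius Gaussian blob radius, px (default 2).
#' @param pixel_size,frame_interval calibration attached to the output.
#' @param window_size intended PIV window, px; displacements above
#'   `window_size / 4` trigger a warning (recovery not guaranteed).
#' @return an [image_sequence()].
#' @export
render_speckle <- function(displacement, shape, n_frames, seed = 1L,
                           speckle_density = 0.02, speckle_radius = 2,
                           pixel_size = 1, frame_interval = 1,
                           window_size = 32) {
  if (n_frames < 1 || n_frames != round(n_frames))
    stop("'n_frames' must be a positive integer", call. = FALSE)
  h <- shape[1]; w <- shape[2]
  if (is.numeric(displacement) && length(displacement) == 2) {
    umat <- matrix(displacement[1], h, w)
    vmat <- matrix(displacement[2], h, w)
  } else if (is.list(displacement) && all(c("u", "v") %in% names(displacement))) {
    umat <- as.matrix(displacement$u); vmat <- as.matrix(displacement$v)
    if (!identical(dim(umat), c(h, w)) || !identical(dim(vmat), c(h, w)))
      stop("displacement matrices must match 'shape'", call. = FALSE)
  } else {
    stop("'displacement' must be length-2 numeric or list(u =, v =)", call. = FALSE)
  }
  if (max(sqrt(umat^2 + vmat^2)) > window_size / 4)
    warning("displacement exceeds a quarter of the PIV window size; ",
            "PIV recovery is not guaranteed", call. = FALSE)
  frames <- vector("list", n_frames)
  frames[[1]] <- with_seed(seed, .speckle_texture(c(h, w), speckle_density,
                                                  speckle_radius))
  if (n_frames > 1) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    # backward warp: content at (r, c) came from (r + v, c - u)
    R <- rows + vmat; C <- cols - umat
    for (t in seq_len(n_frames - 1))
      frames[[t + 1]] <- .sample_periodic(frames[[t]], R, C)
  }
  image_sequence(frames, pixel_size = pixel_size,
                 frame_interval = frame_interval)
}

#' Synthetic tissue with a moving free edge
#'
#' Renders a textured "tissue" occupying the left portion of the frame over
#' a low-amplitude noise background. The tissue's right boundary starts at
#' 60% of the width and moves by `+rate` px/frame (`advance`), stays fixed
#' (`static`) or moves by `-rate` px/frame (`retract`), emulating leading
#' edges that advance under stimulation, stall, or collapse inward. The
#' motion is purely kinematic (the edge is revealed/covered); no retraction
#' mechanics are modeled.
#'
#' @param mode one of `"advance"`, `"static"`, `"retract"`.
#' @param rate edge speed, px/frame >= 0.
#' @param shape `c(rows, cols)` px.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param noise_sd background noise standard deviation (intensity units).
#' @param pixel_size,frame_interval calibration attached to the output.
#' @return list with `images` (an [image_sequence()]) and `edge_px`
#'   (numeric, the true edge x-position in px per frame).
#' @export
make_edge_scenario <- function(mode = c("advance", "static", "retract"),
                               rate = 2, shape = c(160, 320), n_frames = 11,
                               seed = 1L, noise_sd = 0.02,
                               pixel_size = 1, frame_interval = 1) {
  mode <- match.arg(mode)
  if (rate < 0) stop("'rate' must be >= 0", call. = FALSE)
  h <- shape[1]; w <- shape[2]
  s <- switch(mode, advance = 1, static = 0, retract = -1)
  e0 <- round(0.6 * w)
  edge <- e0 + s * rate * (seq_len(n_frames) - 1)
  if (any(edge < 1) || any(edge > w - 1))
    stop("edge leaves the frame; reduce rate or n_frames", call. = FALSE)
  with_seed(seed, {
    tex <- .speckle_texture(c(h, w), density = 0.04, radius = 1.5)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    frames <- lapply(seq_len(n_frames), function(t) {
      mask <- cols <= edge[t]
      bg <- 0.5 + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
      f <- ifelse(mask, tex, bg)
      pmin(pmax(f, 0), 1)
    })
    list(images = image_sequence(frames, pixel_size = pixel_size,
                                 frame_interval = frame_interval),
         edge_px = edge)
  })
}
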