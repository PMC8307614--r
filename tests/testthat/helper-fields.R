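# Shared fixtures and independent brute-force oracles for the metric tests.
# The oracles deliberately use plain loops over vectors, independent of the
# matrix code paths in the package.

uniform_field <- function(u, v, ny = 4, nx = 4, ...) {
  velocity_field(matrix(u, ny, nx), matrix(v, ny, nx), ...)
}

# Field from explicit vector list: one valid row of n nodes.
vectors_field <- function(vecs, ...) {
  u <- matrix(vapply(vecs, `[`, 0, 1), 1)
  v <- matrix(vapply(vecs, `[`, 0, 2), 1)
  velocity_field(u, v, ...)
}

random_field <- function(seed, ny = 16, nx = 16, p_invalid = 0.1,
                         pixel_size = 1.3, frame_interval = 5) {
  set.seed(seed)
  u <- matrix(runif(ny * nx, -2, 2), ny, nx)
  v <- matrix(runif(ny * nx, -2, 2), ny, nx)
  valid <- matrix(runif(ny * nx) > p_invalid, ny, nx)
  velocity_field(u, v, valid = valid, pixel_size = pixel_size,
                 frame_interval = frame_interval, units = "um_min")
}

bf_vectors <- function(field, drop_zero = TRUE) {
  vel <- field_velocities(field)
  out <- list()
  for (i in seq_len(nrow(vel$u))) for (j in seq_len(ncol(vel$u))) {
    if (!field$valid[i, j]) next
    w <- c(vel$u[i, j], vel$v[i, j])
    if (drop_zero && sqrt(sum(w^2)) <= 1e-9) next
    out[[length(out) + 1]] <- w
  }
  out
}

bf_directionality <- function(field) {
  vs <- bf_vectors(field)
  mean(vapply(vs, function(w) w[1] / sqrt(sum(w^2)), 0))
}

bf_coordination <- function(field) {
  vs <- bf_vectors(field)
  s <- c(0, 0)
  for (w in vs) s <- s + w / sqrt(sum(w^2))
  sqrt(sum((s / length(vs))^2))
}

bf_mean_speed <- function(field) {
  vs <- bf_vectors(field, drop_zero = FALSE)
  mean(vapply(vs, function(w) sqrt(sum(w^2)), 0))
}

bf_mean_x_velocity <- function(field) {
  vs <- bf_vectors(field, drop_zero = FALSE)
  mean(vapply(vs, function(w) w[1], 0))
}

bf_neighbor_correlation <- function(field) {
  vel <- field_velocities(field)
  ny <- nrow(vel$u); nx <- ncol(vel$u)
  sims <- c()
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!field$valid[i, j]) next
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    acc <- c(0, 0); k <- 0
    for (r in seq_len(nrow(nb))) {
      a <- nb[r, 1]; b <- nb[r, 2]
      if (a >= 1 && a <= ny && b >= 1 && b <= nx && field$valid[a, b]) {
        acc <- acc + c(vel$u[a, b], vel$v[a, b]); k <- k + 1
      }
    }
    if (k == 0) next
    m <- acc / k
    w <- c(vel$u[i, j], vel$v[i, j])
    if (sqrt(sum(w^2)) <= 1e-9 || sqrt(sum(m^2)) <= 1e-9) next
    sims <- c(sims, sum(w * m) / (sqrt(sum(w^2)) * sqrt(sum(m^2))))
  }
  mean(sims)
}

# Rotate all vectors of a field by angle phi (physical convention).
rotate_field <- function(field, phi) {
  u2 <- cos(phi) * field$u - sin(phi) * field$v
  v2 <- sin(phi) * field$u + cos(phi) * field$v
  velocity_field(u2, v2, x = field$x, y = field$y, valid = field$valid,
                 pixel_size = field$pixel_size,
                 frame_interval = field$frame_interval)
}
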