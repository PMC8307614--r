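# Base-graphics displays of the standard quantities.

#' Plot a kymograph as a heat map
#'
#' Diverging blue-white-red map centered at 0, the conventional display for
#' x-velocity kymographs (red = motion toward +x / the cathode).
#'
#' @param x a `kymograph`.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  vals <- x$values
  lim <- max(abs(vals), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(101)
  graphics::image(x = x$col_centers, y = x$row_times, z = t(vals),
                  zlim = c(-lim, lim), col = pal,
                  xlab = "x (um)", ylab = "time (min)",
                  main = sprintf("%s kymograph (um/min)", x$quantity),
                  ylim = rev(range(x$row_times)), ...)
  invisible(x)
}

#' Plot a metric time series
#'
#' @param x a `metric_series`.
#' @param metrics columns to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.metric_series <- function(x, metrics = c("speed", "x_velocity",
                                              "directionality",
                                              "coordination"), ...) {
  m <- as.matrix(x[, metrics, drop = FALSE])
  graphics::matplot(x$time, m, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "value", ...)
  graphics::legend("topleft", legend = metrics, lty = 1,
                   col = seq_along(metrics), bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot a polar histogram of velocity angles
#'
#' Wedge plot over `(-pi, pi]`; angle 0 (the +x / field axis) points right.
#'
#' @param x a `polar_histogram`.
#' @param ... ignored.
#' @export
plot.polar_histogram <- function(x, ...) {
  f <- x$frequency
  r <- f / max(f)
  n <- length(f)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "velocity angle distribution")
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey70")
  for (i in seq_len(n)) {
    a0 <- x$bin_edges[i]; a1 <- x$bin_edges[i + 1]
    aa <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, r[i] * cos(aa)), c(0, r[i] * sin(aa)),
                      col = "#b2182b88", border = "grey30")
  }
  graphics::segments(-1, 0, 1, 0, col = "grey70", lty = 2)
  invisible(x)
}
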