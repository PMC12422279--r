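# Base-graphics views of the two objects users inspect most: a simulated
# movement realization over the camera grid, and the per-tree prediction
# distribution behind a density estimate.

#' @export
plot.trajectory <- function(x, grid = NULL, ...) {
  graphics::plot(x$positions, type = "l", col = "grey40", asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("Simulated movement, individual %s (%s)",
                                x$individual_id, x$species), ...)
  graphics::points(x$home_center[1], x$home_center[2], pch = 3, col = "blue")
  if (!is.null(grid))
    graphics::points(grid$x_m, grid$y_m, pch = 17, col = "red")
  invisible(x)
}

#' @export
plot.density_estimate <- function(x, ...) {
  d <- x$tree_predictions / x$effective_area_km2
  graphics::hist(d, breaks = 20, freq = FALSE, col = "grey85",
                 border = "white",
                 xlab = "density (individuals/km2)",
                 main = sprintf("%s at %s", x$species, x$site), ...)
  graphics::abline(v = x$density, col = "red", lwd = 2)
  graphics::abline(v = c(x$ci_low, x$ci_high), col = "red", lty = 2)
  invisible(x)
}
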