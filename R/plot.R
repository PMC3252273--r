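# Base-graphics views of worlds, paths, panoramas and familiarity maps,
# in the style of the usual route figures: training paths red,
# recapitulations black, pseudocolour familiarity with heading quivers.

#' Plot a top-down view of a world
#'
#' Tussock and landmark footprints are drawn as grey polygons, the nest as
#' a cross.
#'
#' @param x an `ant_world`.
#' @param xlim,ylim extent; defaults to the central region.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ant_world <- function(x, xlim = x$region[1:2], ylim = x$region[3:4],
                           ...) {
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                 xlab = "x (m, east)", ylab = "y (m, north)", ...)
  keep <- x$object_kind[x$patch_object] != "panorama"
  p <- x$patches[keep, , drop = FALSE]
  if (nrow(p) > 0) {
    graphics::polygon(
      x = as.vector(t(cbind(p[, 1], p[, 4], p[, 7], NA))),
      y = as.vector(t(cbind(p[, 2], p[, 5], p[, 8], NA))),
      col = grDevices::grey(0.55), border = NA)
  }
  graphics::points(x$nest[1], x$nest[2], pch = 3, cex = 1.4, lwd = 2)
  invisible(x)
}

#' Add a path to an existing plot
#'
#' @param x an `ant_path` or `recap_result`.
#' @param col line colour; by convention red for training paths, black for
#'   recapitulations (the default follows the path kind).
#' @param ... passed to [graphics::lines()].
#' @export
plot.ant_path <- function(x, col = NULL, ...) {
  col <- col %||% if (x$kind == "recapitulation") "black" else "red"
  graphics::lines(x$poses$x, x$poses$y, col = col, ...)
  invisible(x)
}

#' @export
plot.recap_result <- function(x, ...) {
  plot.ant_path(x$path, ...)
}

#' Display a panorama or high-resolution view
#'
#' @param v view matrix (17 x 90 panorama or binary raster).
#' @param ... passed to [graphics::image()].
#' @export
plot_view <- function(v, ...) {
  graphics::image(x = seq(-180, 180, length.out = ncol(v) + 1),
                  y = seq(0, 68, length.out = nrow(v) + 1),
                  z = t(v)[, , drop = FALSE],
                  col = grDevices::grey(seq(1, 0, length.out = 64)),
                  xlab = "azimuth (deg, relative to heading)",
                  ylab = "elevation (deg)", useRaster = TRUE, ...)
  invisible(v)
}

#' Plot a familiarity map with heading quivers
#'
#' Pseudocolour best-familiarity surface (darker hues = more familiar)
#' with arrows showing the best heading at each grid point.
#'
#' @param x a `familiarity_map`.
#' @param arrows draw the heading quivers.
#' @param ... passed to [graphics::image()].
#' @export
plot.familiarity_map <- function(x, arrows = TRUE, ...) {
  graphics::image(x$x, x$y, -x$familiarity,
                  col = grDevices::hcl.colors(64, "YlOrRd"),
                  xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  if (arrows) {
    len <- 0.35 * min(diff(x$x[1:2]), diff(x$y[1:2]))
    g <- expand.grid(i = seq_along(x$x), j = seq_along(x$y))
    th <- x$heading[cbind(g$i, g$j)] * pi / 180
    graphics::arrows(x$x[g$i], x$y[g$j],
                     x$x[g$i] + len * sin(th), x$y[g$j] + len * cos(th),
                     length = 0.03, col = "white")
  }
  invisible(x)
}
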