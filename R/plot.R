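# Minimal polar FDH plot helper (base graphics). Presentation aid only.

#' Plot an axial FDH in polar coordinates
#'
#' Mirrors the histogram across 180 degrees so the axial distribution reads
#' as the familiar symmetric polar rose.
#'
#' @param x An [build_fdh()] histogram.
#' @param col Line color.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.axial_fdh <- function(x, col = "steelblue", ...) {
  th <- deg2rad(c(x$bin_centers, x$bin_centers + 180, x$bin_centers[1]))
  r <- c(x$mass, x$mass, x$mass[1])
  graphics::plot(r * cos(th), r * sin(th), type = "l", col = col, asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  graphics::segments(-max(r), 0, max(r), 0, col = "grey70", lty = 3)
  graphics::segments(0, -max(r), 0, max(r), col = "grey70", lty = 3)
  invisible(x)
}
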