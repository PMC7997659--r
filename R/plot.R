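#' Plot a pore-radius profile
#'
#' Radius as a function of channel position (z; 0 at the M3-bundle
#' centroid, +z extracellular), with the closed-channel cutoff marked.
#'
#' @param x A `pore_profile`.
#' @param cutoff Dashed reference line, Angstrom (default from the
#'   profile's parameters).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @importFrom graphics plot abline
#' @export
plot.pore_profile <- function(x, cutoff = NULL, ...) {
  p <- attr(x, "params")
  if (is.null(cutoff)) cutoff <- p$closed_cutoff
  plot(x$radius, x$z, type = "l", xlab = "pore radius (Å)",
       ylab = "channel position z (Å)", ...)
  graphics::abline(v = cutoff, lty = 2, col = "red")
  invisible(x)
}

#' Plot a per-residue deviation profile
#'
#' @param x A `deviation_profile`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.deviation_profile <- function(x, ...) {
  plot(x$res_seq, x$value, type = "b", pch = 16, cex = 0.6,
       xlab = "residue", ylab = paste0(attr(x, "kind"), " (Å)"),
       main = paste("position", attr(x, "position")), ...)
  invisible(x)
}
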