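#' Density plot of the two score classes with optional decision zones
#'
#' Minimal base-graphics display of the mixed densities (diseased and
#' non-diseased) with the inconclusive band shaded, in the style commonly
#' used to present trichotomized markers.
#'
#' @param x A `labeled_sample`.
#' @param zones Optional `decision_zones` to overlay.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.labeled_sample <- function(x, zones = NULL, ...) {
  cl <- check_both_classes(x)
  d0 <- stats::density(cl$s0)
  d1 <- stats::density(cl$s1)
  graphics::plot(d0, col = "steelblue", lwd = 2,
                 xlim = range(d0$x, d1$x), ylim = range(0, d0$y, d1$y),
                 main = "Class score densities", xlab = "score", ...)
  graphics::lines(d1, col = "firebrick", lwd = 2)
  if (!is.null(zones)) {
    graphics::abline(v = c(zones$lower, zones$upper), lty = 2)
  }
  graphics::legend("topright", legend = c("non-diseased", "diseased"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}
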