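#' Plot a Timer-Angle density
#'
#' @param density an [AngleDensity-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotAngleDensity <- function(density, ...) {
  stopifnot(methods::is(density, "AngleDensity"))
  graphics::plot(density@grid, density@density, type = "l",
                 xlab = "Timer-Angle (degrees)", ylab = "density",
                 xlim = c(0, 90), ...)
  graphics::abline(v = c(30, 60), lty = 3, col = "grey50")
  invisible(density)
}

#' Blue-Red plane scatter of gated events
#'
#' Raw blue versus red fluorescence on log-like axes (asinh), positives
#' highlighted, thresholds drawn.
#'
#' @param events a [TimerEvents-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotTimerPlane <- function(events, ...) {
  stopifnot(methods::is(events, "TimerEvents"))
  d <- events@data
  tr <- function(x) asinh(x / 150)
  graphics::plot(tr(d$blue), tr(d$red),
                 col = ifelse(d$positive, "#1f78b4", "grey70"), pch = 16,
                 cex = 0.4, xlab = "Timer-Blue (asinh)",
                 ylab = "Timer-Red (asinh)", ...)
  graphics::abline(v = tr(events@thresholds@blue),
                   h = tr(events@thresholds@red), lty = 2, col = "grey40")
  invisible(events)
}
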