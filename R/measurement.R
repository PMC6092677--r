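#' Cytometer measurement model
#'
#' Maps true per-cell protein amounts to measured fluorescence:
#' `signal = signalScale * protein * lognormal(cv) + Normal(afMean, afSd)`,
#' floored at 0. The additive normal term emulates autofluorescence
#' background (so control-based thresholding is exercised realistically);
#' the multiplicative lognormal term emulates detector and staining noise.
#'
#' The default calibration places the steady-state blue signal of a
#' persistent expressor (unit transcription rate, default kinetics) at about
#' 50 times the expected 99.9%-quantile threshold of the negative control,
#' i.e. clearly Timer-positive.
#'
#' @slot autofluorescenceMean,autofluorescenceSd named numeric (blue, red),
#'   fluorescence units.
#' @slot multiplicativeCv coefficient of variation of the lognormal
#'   multiplicative noise (dimensionless).
#' @slot signalScale named numeric (blue, red), fluorescence units per
#'   protein unit.
#' @examples
#' measurementModel()
#' measurementOff() # deterministic: scaling only, no background or noise
#' @export
setClass("MeasurementModel",
  slots = c(
    autofluorescenceMean = "numeric",
    autofluorescenceSd = "numeric",
    multiplicativeCv = "numeric",
    signalScale = "numeric"
  )
)

.chan2 <- function(x, what) {
  if (length(x) == 1L) x <- c(blue = unname(x), red = unname(x))
  if (is.null(names(x))) names(x) <- c("blue", "red")
  if (!all(c("blue", "red") %in% names(x))) {
    stop(what, " must be named with 'blue' and 'red'")
  }
  x[c("blue", "red")]
}

setValidity("MeasurementModel", function(object) {
  msgs <- character()
  if (any(object@autofluorescenceSd < 0)) msgs <- c(msgs, "sd must be >= 0")
  if (object@multiplicativeCv < 0) msgs <- c(msgs, "cv must be >= 0")
  if (any(object@signalScale <= 0)) msgs <- c(msgs, "signal scales must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @param autofluorescenceMean,autofluorescenceSd,multiplicativeCv,signalScale
#'   see the corresponding slots; scalars are recycled to both channels.
#' @rdname MeasurementModel-class
#' @export
measurementModel <- function(autofluorescenceMean = c(blue = 100, red = 100),
                             autofluorescenceSd = c(blue = 25, red = 25),
                             multiplicativeCv = 0.1,
                             signalScale = c(blue = 1500, red = 1500)) {
  methods::new("MeasurementModel",
    autofluorescenceMean = .chan2(autofluorescenceMean, "autofluorescenceMean"),
    autofluorescenceSd = .chan2(autofluorescenceSd, "autofluorescenceSd"),
    multiplicativeCv = multiplicativeCv,
    signalScale = .chan2(signalScale, "signalScale")
  )
}

#' @rdname MeasurementModel-class
#' @export
measurementOff <- function(signalScale = c(blue = 1500, red = 1500)) {
  measurementModel(
    autofluorescenceMean = c(blue = 0, red = 0),
    autofluorescenceSd = c(blue = 0, red = 0),
    multiplicativeCv = 0,
    signalScale = signalScale
  )
}

setMethod("show", "MeasurementModel", function(object) {
  cat("MeasurementModel\n")
  cat(sprintf("  autofluorescence: blue %g +/- %g, red %g +/- %g\n",
    object@autofluorescenceMean[["blue"]], object@autofluorescenceSd[["blue"]],
    object@autofluorescenceMean[["red"]], object@autofluorescenceSd[["red"]]))
  cat(sprintf("  multiplicative CV: %g\n", object@multiplicativeCv))
  cat(sprintf("  signal scale: blue %g, red %g per protein unit\n",
    object@signalScale[["blue"]], object@signalScale[["red"]]))
  invisible(object)
})

## Measured fluorescence of true protein amounts in one channel.
## Draws multiplicative then additive noise (in that order, for reproducible
## RNG streams); deterministic when cv and sd are both 0.
.measureChannel <- function(true, noise, channel) {
  n <- length(true)
  sig <- noise@signalScale[[channel]] * true
  if (noise@multiplicativeCv > 0) {
    sig <- sig * rlnormMean1(n, noise@multiplicativeCv)
  }
  if (noise@autofluorescenceSd[[channel]] > 0 ||
      noise@autofluorescenceMean[[channel]] != 0) {
    sig <- sig + stats::rnorm(n, noise@autofluorescenceMean[[channel]],
                              noise@autofluorescenceSd[[channel]])
  }
  pmax(sig, 0)
}
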