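#' Half-life fit
#'
#' Result of a decay regression: the half-life in hours together with the
#' regression diagnostics on the fitted scale. Non-decaying series are
#' flagged (`decaying = FALSE`) and report an infinite half-life rather than
#' an error.
#'
#' @slot halflife hours (`Inf` for a flagged non-decaying series).
#' @slot slope,intercept OLS coefficients on the fitted scale.
#' @slot pearsonR Pearson correlation of time and response on the fitted
#'   scale (`NA` for a constant series).
#' @slot rSquared squared correlation.
#' @slot scale `"log_linear"`, `"linear"` or `"ct"`.
#' @slot decaying logical flag.
#' @slot n number of points used.
#' @export
setClass("HalfLifeFit",
  slots = c(halflife = "numeric", slope = "numeric", intercept = "numeric",
            pearsonR = "numeric", rSquared = "numeric", scale = "character",
            decaying = "logical", n = "integer")
)

setValidity("HalfLifeFit", function(object) {
  msgs <- character()
  if (isTRUE(object@decaying) && !(object@halflife > 0)) {
    msgs <- c(msgs, "half-life of a decaying series must be > 0")
  }
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)) {
    msgs <- c(msgs, "r-squared must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HalfLifeFit", function(object) {
  cat(sprintf("HalfLifeFit (%s scale, n = %d)\n", object@scale, object@n))
  if (object@decaying) {
    cat(sprintf("  half-life: %.4g h\n", object@halflife))
  } else {
    cat("  series not decaying (half-life reported as Inf)\n")
  }
  cat(sprintf("  slope %.4g, intercept %.4g, r = %.4g, r^2 = %.4g\n",
    object@slope, object@intercept, object@pearsonR, object@rSquared))
  invisible(object)
})

#' @rdname HalfLifeFit-class
#' @param x a `HalfLifeFit`.
#' @export
setMethod("halflife", "HalfLifeFit", function(x) x@halflife)

.seriesXY <- function(series) {
  if (methods::is(series, "DecaySeries")) {
    list(t = series@times, v = series@values)
  } else if (is.data.frame(series)) {
    tc <- intersect(c("time_h", "time", "times"), names(series))[1L]
    vc <- intersect(c("value", "values"), names(series))[1L]
    if (is.na(tc) || is.na(vc)) stop("data.frame series needs time and value columns")
    list(t = series[[tc]], v = series[[vc]])
  } else {
    stop("series must be a DecaySeries or a tidy data.frame")
  }
}

.olsFit <- function(t, y, scale, halflifeFromSlope, decayingIf) {
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r <- if (stats::sd(y) > 0) stats::cor(t, y) else NA_real_
  decaying <- decayingIf(slope)
  methods::new("HalfLifeFit",
    halflife = if (decaying) halflifeFromSlope(slope, intercept) else Inf,
    slope = slope, intercept = intercept,
    pearsonR = r, rSquared = if (is.na(r)) NA_real_ else r^2,
    scale = scale, decaying = decaying, n = length(t)
  )
}

#' Estimate a half-life by log-linear regression
#'
#' Ordinary least squares of `ln(value)` on time; the half-life is
#' `ln(2) / (-slope)`. Replicates enter the regression individually. A
#' non-decaying series (slope >= 0) is flagged and reports `Inf`.
#'
#' @param series a [DecaySeries-class] or tidy data.frame with time and
#'   value columns; at least 3 points, all values > 0.
#' @return A [HalfLifeFit-class].
#' @examples
#' t <- c(0, 2, 4, 6, 8, 12)
#' halflife(fitLogLinearHalflife(decaySeries(t, 2^(-t / 4.1))))
#' @export
fitLogLinearHalflife <- function(series) {
  xy <- .seriesXY(series)
  if (length(xy$t) < 3L) stop("need at least 3 time points")
  if (any(xy$v <= 0)) stop("log-linear fit requires strictly positive values")
  .olsFit(xy$t, log(xy$v), "log_linear",
          function(slope, intercept) log(2) / (-slope),
          function(slope) is.finite(slope) && slope < 0)
}

#' Estimate a half-life by linear-scale regression
#'
#' OLS of the raw values on time; the half-life is the time at which the
#' fitted line falls to half its intercept, `-intercept / (2 * slope)`.
#' Provided because published decay fits are sometimes performed on the
#' linear scale; on noise-free exponential input sampled over about one
#' half-life the two estimators closely agree.
#'
#' @inheritParams fitLogLinearHalflife
#' @return A [HalfLifeFit-class].
#' @export
fitLinearHalflife <- function(series) {
  xy <- .seriesXY(series)
  if (length(xy$t) < 3L) stop("need at least 3 time points")
  .olsFit(xy$t, xy$v, "linear",
          function(slope, intercept) -intercept / (2 * slope),
          function(slope) is.finite(slope) && slope < 0)
}

#' Estimate an mRNA half-life from a qPCR Ct time course
#'
#' OLS of Ct on time after a transcription blockade. One Ct cycle
#' corresponds to one halving of template, so the half-life is `1 / slope`
#' hours. A non-rising Ct series (slope <= 0, template not decaying) is
#' flagged.
#'
#' @inheritParams fitLogLinearHalflife
#' @return A [HalfLifeFit-class].
#' @examples
#' t <- c(0, 1, 2, 4)
#' halflife(fitCtHalflife(decaySeries(t, 20 + t / 1.14, readout = "ct")))
#' @export
fitCtHalflife <- function(series) {
  xy <- .seriesXY(series)
  if (length(xy$t) < 3L) stop("need at least 3 time points")
  if (any(!is.finite(xy$v))) stop("Ct values must be finite")
  .olsFit(xy$t, xy$v, "ct",
          function(slope, intercept) 1 / slope,
          function(slope) is.finite(slope) && slope > 0)
}

#' Housekeeping-normalised relative expression
#'
#' The delta-Ct fold change `2^-(ctTarget - ctReference)` of a target gene
#' relative to a housekeeping reference.
#'
#' @param ctTarget,ctReference finite Ct values (vectorised).
#' @return Dimensionless fold change.
#' @examples
#' relativeExpression(21, 20) # one cycle later than the reference: 0.5
#' @export
relativeExpression <- function(ctTarget, ctReference) {
  if (any(!is.finite(ctTarget)) || any(!is.finite(ctReference))) {
    stop("Ct values must be finite")
  }
  2^(-(ctTarget - ctReference))
}
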