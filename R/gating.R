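#' Channel thresholds derived from a negative control
#'
#' Per-channel Timer-positivity thresholds with their provenance: the
#' control quantile used and the control sample id.
#'
#' @slot blue,red threshold fluorescence values (>= 0).
#' @slot quantile control quantile used.
#' @slot controlId identifier of the control sample.
#' @export
setClass("ChannelThresholds",
  slots = c(blue = "numeric", red = "numeric",
            quantile = "numeric", controlId = "character")
)

setValidity("ChannelThresholds", function(object) {
  if (object@blue < 0 || object@red < 0) return("thresholds must be >= 0")
  TRUE
})

setMethod("show", "ChannelThresholds", function(object) {
  cat(sprintf(
    "ChannelThresholds: blue %.4g, red %.4g (quantile %.4g of control '%s')\n",
    object@blue, object@red, object@quantile, object@controlId))
  invisible(object)
})

#' Derive Timer-positivity thresholds from a negative control
#'
#' The threshold of each channel is the empirical `quantile` of the control
#' fluorescence (type-1 order statistic, so a direct sort reproduces it),
#' floored at 0. Events of a stained sample are later called Timer-positive
#' when they exceed the threshold in either channel.
#'
#' @param control a [TimerSample-class] (its control table is used) or a
#'   data.frame with `blue` and `red` columns; at least 100 events.
#' @param quantile control quantile in (0.5, 1); default 0.999.
#' @param controlId provenance label.
#' @return A [ChannelThresholds-class].
#' @export
deriveThresholds <- function(control, quantile = 0.999, controlId = "control") {
  df <- if (methods::is(control, "TimerSample")) controlTable(control) else control
  if (!all(c("blue", "red") %in% names(df))) {
    stop("control must have 'blue' and 'red' columns")
  }
  if (nrow(df) < 100L) stop("control must have at least 100 events")
  if (quantile <= 0.5 || quantile >= 1) stop("quantile must lie in (0.5, 1)")
  methods::new("ChannelThresholds",
    blue = max(0, quantileType1(df$blue, quantile)),
    red = max(0, quantileType1(df$red, quantile)),
    quantile = quantile, controlId = controlId
  )
}

#' Gated and transformed Timer events
#'
#' Per-event table after gating (and, once [timerTransform()] has run,
#' normalisation and the trigonometric transform). The `data` slot holds
#' `event_id`, raw `blue`/`red`, the `positive` flag, and after transform
#' `nblue`/`nred` (normalised, in [0, 1]), `timer_angle` (degrees, positive
#' events only) and `timer_intensity`; marker columns are carried through.
#'
#' @slot data per-event data.frame.
#' @slot thresholds the [ChannelThresholds-class] used for gating.
#' @slot reference per-channel normalisation references (NA before
#'   transform).
#' @slot normQuantile quantile defining the references (NA before
#'   transform).
#' @slot transformed logical.
#' @slot sampleId sample label.
#' @export
setClass("TimerEvents",
  slots = c(data = "data.frame", thresholds = "ChannelThresholds",
            reference = "numeric", normQuantile = "numeric",
            transformed = "logical", sampleId = "character")
)

setValidity("TimerEvents", function(object) {
  msgs <- character()
  need <- c("event_id", "blue", "red", "positive")
  if (!all(need %in% names(object@data))) {
    msgs <- c(msgs, "data must have columns event_id, blue, red, positive")
  }
  if (isTRUE(object@transformed)) {
    d <- object@data
    if (!all(c("nblue", "nred", "timer_angle", "timer_intensity") %in% names(d))) {
      msgs <- c(msgs, "transformed events must carry nblue, nred, timer_angle, timer_intensity")
    } else {
      ang <- d$timer_angle[d$positive]
      if (any(!is.na(ang) & (ang < 0 | ang > 90))) {
        msgs <- c(msgs, "timer_angle must lie in [0, 90]")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TimerEvents", function(object) {
  cat(sprintf("TimerEvents '%s': %d events, %d Timer-positive%s\n",
    object@sampleId, nrow(object@data), sum(object@data$positive),
    if (object@transformed) ", transformed" else ""))
  invisible(object)
})

#' @rdname TimerEvents-class
#' @param x a `TimerEvents`.
#' @export
setMethod("eventTable", "TimerEvents", function(x) x@data)

#' Number of Timer-positive events
#' @param x a [TimerEvents-class].
#' @export
nPositive <- function(x) {
  stopifnot(methods::is(x, "TimerEvents"))
  sum(x@data$positive)
}

#' Gate Timer-positive events against control thresholds
#'
#' An event is Timer-positive when it strictly exceeds the threshold in the
#' blue or the red channel (ties at the threshold count as negative).
#'
#' @param frame a [TimerSample-class] (its event table is used) or a
#'   data.frame with `blue` and `red` columns.
#' @param thresholds a [ChannelThresholds-class] derived from the matching
#'   negative control.
#' @param sampleId label stored on the result.
#' @return A [TimerEvents-class] with positivity flags set.
#' @export
gateTimerPositive <- function(frame, thresholds, sampleId = NULL) {
  stopifnot(methods::is(thresholds, "ChannelThresholds"))
  if (methods::is(frame, "TimerSample")) {
    if (is.null(sampleId)) sampleId <- frame@metadata$label %||% "sample"
    frame <- eventTable(frame)
  }
  if (!all(c("blue", "red") %in% names(frame))) {
    stop("frame must have 'blue' and 'red' columns")
  }
  if (!"event_id" %in% names(frame)) frame$event_id <- seq_len(nrow(frame))
  df <- frame
  df$positive <- df$blue > thresholds@blue | df$red > thresholds@red
  methods::new("TimerEvents",
    data = df, thresholds = thresholds,
    reference = c(blue = NA_real_, red = NA_real_),
    normQuantile = NA_real_, transformed = FALSE,
    sampleId = sampleId %||% "sample"
  )
}

#' Timer-Angle and Timer-Intensity of normalised coordinates
#'
#' The angle from the blue axis in the normalised Blue-Red plane, in
#' degrees: 0 when normalised red is 0 (pure blue, a new expressor), 90 when
#' normalised blue is 0 (pure red, arrested), 45 at the balanced state.
#' `timerIntensity()` is the Euclidean norm of the normalised coordinates.
#' Both are `NA` when both coordinates are 0.
#'
#' @param nblue,nred normalised coordinates (>= 0, vectorised).
#' @return Degrees in [0, 90], or intensity >= 0.
#' @examples
#' timerAngle(c(1, 0, 1, 1), c(0, 1, 1, sqrt(3)))
#' @export
timerAngle <- function(nblue, nred) {
  stopifnot(length(nblue) == length(nred))
  if (any(nblue < 0, na.rm = TRUE) || any(nred < 0, na.rm = TRUE)) {
    stop("normalised coordinates must be >= 0")
  }
  ang <- atan2(nred, nblue) * 180 / pi
  ang[nblue == 0 & nred == 0] <- NA_real_
  ang
}

#' @rdname timerAngle
#' @export
timerIntensity <- function(nblue, nred) {
  out <- sqrt(nblue^2 + nred^2)
  out[nblue == 0 & nred == 0] <- NA_real_
  out
}

#' Normalise channels and apply the trigonometric Timer transform
#'
#' Per channel, the threshold is subtracted and the result is scaled by the
#' `normQuantile` quantile of the Timer-positive events of that channel
#' (the normalisation reference), then clipped to [0, 1]:
#' `n = min(1, max(0, raw - threshold) / (reference - threshold))`.
#' Timer-Angle and Timer-Intensity are computed for positive events;
#' negative events keep `NA` angles and intensities.
#'
#' A sample whose positive events all sit at or below threshold in one
#' channel (for example a purely arrested population, blue-negative
#' throughout) cannot define a scale for that channel from its own events;
#' this raises a degenerate-reference error. Such samples are analysed
#' batch-style by passing a `reference` derived from a sample that spans
#' the dynamic range.
#'
#' @param events a gated [TimerEvents-class] with at least one positive
#'   event.
#' @param normQuantile reference quantile of positive events, default
#'   0.975 (robust to the brightest outliers).
#' @param reference optional named numeric `c(blue=, red=)` of
#'   normalisation references (fluorescence units), overriding the
#'   per-sample quantile; both must exceed the thresholds.
#' @return The [TimerEvents-class] with normalised values, angle and
#'   intensity filled in.
#' @export
timerTransform <- function(events, normQuantile = 0.975, reference = NULL) {
  stopifnot(methods::is(events, "TimerEvents"))
  if (normQuantile <= 0 || normQuantile > 1) {
    stop("normQuantile must lie in (0, 1]")
  }
  df <- events@data
  pos <- df$positive
  if (!any(pos)) stop("no Timer-positive events to transform")
  thr <- c(blue = events@thresholds@blue, red = events@thresholds@red)
  if (is.null(reference)) {
    ref <- c(
      blue = quantileType1(df$blue[pos], normQuantile),
      red = quantileType1(df$red[pos], normQuantile)
    )
  } else {
    ref <- .chan2(reference, "reference")
    normQuantile <- NA_real_
  }
  for (ch in c("blue", "red")) {
    if (!(ref[[ch]] > thr[[ch]])) {
      stop("degenerate normalisation reference in the ", ch,
           " channel: reference quantile does not exceed the threshold")
    }
  }
  nblue <- pmin(1, pmax(0, df$blue - thr[["blue"]]) / (ref[["blue"]] - thr[["blue"]]))
  nred <- pmin(1, pmax(0, df$red - thr[["red"]]) / (ref[["red"]] - thr[["red"]]))
  df$nblue <- nblue
  df$nred <- nred
  df$timer_angle <- NA_real_
  df$timer_intensity <- NA_real_
  df$timer_angle[pos] <- timerAngle(nblue[pos], nred[pos])
  df$timer_intensity[pos] <- timerIntensity(nblue[pos], nred[pos])
  methods::initialize(events,
    data = df, reference = ref, normQuantile = normQuantile,
    transformed = TRUE
  )
}
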