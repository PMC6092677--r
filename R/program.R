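#' Piecewise-constant transcription programs
#'
#' A `TranscriptionProgram` encodes the transcription rate of the reporter
#' gene as a piecewise-constant function of time (hours). Time 0 is the
#' start of the cell's history; outside all segments the rate is 0.
#'
#' Named constructors build the four canonical regimes:
#' \describe{
#'   \item{`programNewOnset(t0)`}{silent until `t0`, then constant
#'     transcription — a newly induced expressor.}
#'   \item{`programPersistent()`}{constant transcription from time 0 —
#'     a persistent expressor.}
#'   \item{`programArrested(tStop)`}{constant transcription from 0 until
#'     `tStop`, then silent — an arrested expressor.}
#'   \item{`programIntermittent(period, dutyCycle)`}{transcription in bursts:
#'     on for `dutyCycle * period` hours at the start of each period.}
#' }
#'
#' @slot segments data.frame with columns `start`, `end`, `rate`
#'   (non-overlapping, ordered; rates >= 0, times in hours).
#'
#' @examples
#' p <- programIntermittent(period = 24, dutyCycle = 0.25)
#' transcriptionRate(p, c(0, 5, 7, 23.9, 24.1))
#' @export
setClass("TranscriptionProgram", slots = c(segments = "data.frame"))

setValidity("TranscriptionProgram", function(object) {
  seg <- object@segments
  msgs <- character()
  if (!all(c("start", "end", "rate") %in% names(seg))) {
    return("segments must have columns start, end, rate")
  }
  if (nrow(seg)) {
    if (any(!is.finite(seg$start)) || any(seg$start < 0)) {
      msgs <- c(msgs, "segment starts must be finite and >= 0")
    }
    if (any(seg$end <= seg$start)) {
      msgs <- c(msgs, "segment ends must exceed their starts")
    }
    if (any(!is.finite(seg$rate)) || any(seg$rate < 0)) {
      msgs <- c(msgs, "rates must be finite and >= 0")
    }
    if (nrow(seg) > 1L) {
      o <- order(seg$start)
      if (any(seg$end[o][-nrow(seg)] > seg$start[o][-1L] + 1e-12)) {
        msgs <- c(msgs, "segments must not overlap")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @param start,end,rate numeric vectors of equal length defining the
#'   segments: transcription at `rate` (units per hour) on `[start, end)`.
#' @rdname TranscriptionProgram-class
#' @export
transcriptionProgram <- function(start, end, rate) {
  seg <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    rate = as.numeric(rate))
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  methods::new("TranscriptionProgram", segments = seg)
}

#' @param t0 onset time in hours.
#' @rdname TranscriptionProgram-class
#' @export
programNewOnset <- function(t0 = 0, rate = 1) {
  transcriptionProgram(t0, Inf, rate)
}

#' @rdname TranscriptionProgram-class
#' @export
programPersistent <- function(rate = 1) {
  transcriptionProgram(0, Inf, rate)
}

#' @param tStop arrest time in hours.
#' @rdname TranscriptionProgram-class
#' @export
programArrested <- function(tStop, rate = 1) {
  stopifnot(is.finite(tStop), tStop > 0)
  transcriptionProgram(0, tStop, rate)
}

#' @param period burst period in hours.
#' @param dutyCycle fraction of each period spent transcribing, in (0, 1].
#' @param horizon last time (hours) up to which bursts are generated.
#' @rdname TranscriptionProgram-class
#' @export
programIntermittent <- function(period, dutyCycle, rate = 1, horizon = 2400) {
  stopifnot(period > 0, dutyCycle > 0, dutyCycle <= 1, horizon > period)
  if (dutyCycle == 1) return(transcriptionProgram(0, horizon, rate))
  starts <- seq(0, horizon, by = period)
  transcriptionProgram(starts, starts + dutyCycle * period, rate)
}

#' Transcription rate at given times
#'
#' @param program a [TranscriptionProgram-class].
#' @param t numeric vector of times (hours).
#' @return Numeric vector of rates; 0 outside all segments. Segments are
#'   half-open `[start, end)`.
#' @export
transcriptionRate <- function(program, t) {
  stopifnot(methods::is(program, "TranscriptionProgram"))
  seg <- program@segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    hit <- t >= seg$start[i] & t < seg$end[i]
    out[hit] <- seg$rate[i]
  }
  out
}

setMethod("show", "TranscriptionProgram", function(object) {
  seg <- object@segments
  cat(sprintf("TranscriptionProgram with %d segment(s)\n", nrow(seg)))
  n <- min(nrow(seg), 5L)
  for (i in seq_len(n)) {
    cat(sprintf("  [%g, %g) h at rate %g\n", seg$start[i], seg$end[i], seg$rate[i]))
  }
  if (nrow(seg) > n) cat(sprintf("  ... %d more\n", nrow(seg) - n))
  invisible(object)
})
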