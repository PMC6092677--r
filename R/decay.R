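#' Decay time series
#'
#' One readout of a blockade or washout experiment: times in hours and the
#' readout values, with replicate identifiers. Readout kinds are `"mfi"`
#' (fluorescence intensity), `"percent_positive"` (0-100), and `"ct"`
#' (qPCR cycle-threshold values).
#'
#' @slot times hours (sorted within replicate).
#' @slot values readout values.
#' @slot readout one of `"mfi"`, `"percent_positive"`, `"ct"`.
#' @slot replicate integer replicate ids.
#' @export
setClass("DecaySeries",
  slots = c(times = "numeric", values = "numeric",
            readout = "character", replicate = "integer")
)

setValidity("DecaySeries", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (length(object@values) != n || length(object@replicate) != n) {
    msgs <- c(msgs, "times, values and replicate must have equal length")
  }
  if (!object@readout %in% c("mfi", "percent_positive", "ct")) {
    msgs <- c(msgs, "readout must be 'mfi', 'percent_positive' or 'ct'")
  }
  if (any(!is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (object@readout == "percent_positive" &&
      (any(object@values < 0) || any(object@values > 100))) {
    msgs <- c(msgs, "percentages must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param times,values,readout,replicate see the corresponding slots;
#'   `replicate` defaults to a single replicate.
#' @rdname DecaySeries-class
#' @export
decaySeries <- function(times, values, readout = "mfi",
                        replicate = rep(1L, length(times))) {
  methods::new("DecaySeries",
    times = as.numeric(times), values = as.numeric(values),
    readout = readout, replicate = as.integer(replicate)
  )
}

#' @rdname DecaySeries-class
#' @param x a `DecaySeries`.
#' @export
as.data.frame.DecaySeries <- function(x, ...) {
  data.frame(time_h = x@times, readout = x@readout,
             value = x@values, replicate = x@replicate)
}

setMethod("show", "DecaySeries", function(object) {
  cat(sprintf("DecaySeries (%s): %d points, %d replicate(s), t in [%g, %g] h\n",
    object@readout, length(object@times), length(unique(object@replicate)),
    min(object@times), max(object@times)))
  invisible(object)
})

#' Write decay series to tidy CSV
#'
#' Columns `time_h`, `readout`, `value`, `replicate`; a list of series is
#' stacked into one file.
#' @param x a [DecaySeries-class] or a list of them.
#' @param path file path.
#' @export
writeDecayCsv <- function(x, path) {
  if (methods::is(x, "DecaySeries")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate half-life calibration experiments
#'
#' Three blockade designs used to calibrate the Timer cascade:
#' \describe{
#'   \item{`"chx"`}{translation blockade (cycloheximide). Cells are brought
#'     to the state reached after `stimulationHours` of persistent
#'     transcription, then protein synthesis stops at t = 0. Blue
#'     fluorescence decays exponentially at the blue-loss rate; red
#'     transiently rises (maturation of the remaining blue pool outpaces the
#'     slow red decay) before declining.}
#'   \item{`"red_washout"`}{a sorted pure-red population cultured without
#'     stimulation: red decays exponentially at the red rate.}
#'   \item{`"actd"`}{transcription blockade (actinomycin D) read out by
#'     qPCR: template halves every mRNA half-life, so
#'     `Ct(t) = ct0 + t / mrnaHalflife` (one cycle per halving).}
#' }
#'
#' With `noise = NULL` the readouts are exact (MFI proportional to the true
#' amounts; Ct exactly linear). With a measurement model, MFI values carry
#' replicate-level lognormal noise at its `multiplicativeCv`, Ct values get
#' additive normal noise (`ctNoiseSd` cycles), and percent-positive readouts
#' are emitted from a heterogeneous population (`nCells` cells, lognormal
#' rate CV `rateCv`) gated at the expected 99.9% autofluorescence quantile.
#'
#' @param kind `"chx"`, `"red_washout"` or `"actd"`.
#' @param params a [TimerKineticParams-class].
#' @param sampleTimes sampling times in hours, including 0.
#' @param noise a [MeasurementModel-class] or `NULL` for noise-free.
#' @param nReplicates replicates per time point.
#' @param seed integer seed for the noise draws.
#' @param stimulationHours hours of persistent transcription before the
#'   translation blockade (chx).
#' @param ct0 Ct value at t = 0 (actd).
#' @param redInit initial red amount, protein units (red_washout).
#' @param nCells population size behind percent-positive readouts.
#' @param rateCv per-cell rate CV behind percent-positive readouts.
#' @return Named list of [DecaySeries-class] objects: `blue_mfi`, `red_mfi`
#'   (and with noise, `blue_pct`, `red_pct`) for chx; `red_mfi` for
#'   red_washout; `ct` for actd.
#' @examples
#' dec <- simulateDecayExperiment("chx", sampleTimes = c(0, 2, 4, 6, 8, 12))
#' fitLogLinearHalflife(dec$blue_mfi)
#' @export
simulateDecayExperiment <- function(kind = c("chx", "red_washout", "actd"),
                                    params = timerKineticParams(),
                                    sampleTimes,
                                    noise = NULL,
                                    nReplicates = 1L,
                                    seed = NULL,
                                    stimulationHours = 48,
                                    ct0 = 20,
                                    redInit = 10,
                                    nCells = 200L,
                                    rateCv = 0.3,
                                    ctNoiseSd = 0.1) {
  kind <- match.arg(kind)
  stopifnot(methods::is(params, "TimerKineticParams"))
  if (length(sampleTimes) == 0L || min(sampleTimes) != 0) {
    stop("sampleTimes must be non-empty and include 0")
  }
  sampleTimes <- sort(as.numeric(sampleTimes))
  nReplicates <- as.integer(nReplicates)
  stopifnot(nReplicates >= 1L)
  noisy <- !is.null(noise)
  scale <- if (noisy) noise@signalScale else measurementOff()@signalScale
  nt <- length(sampleTimes)
  tRep <- rep(sampleTimes, each = nReplicates)
  repId <- rep(seq_len(nReplicates), times = nt)

  mfiSeries <- function(trueAmounts, channel) {
    v <- scale[[channel]] * rep(trueAmounts, each = nReplicates)
    if (noisy && noise@multiplicativeCv > 0) {
      v <- v * rlnormMean1(length(v), noise@multiplicativeCv)
    }
    decaySeries(tRep, v, "mfi", repId)
  }

  withSeed(seed, {
    if (kind == "actd") {
      ct <- ct0 + tRep / params@mrnaHalflife
      if (noisy && ctNoiseSd > 0) ct <- ct + stats::rnorm(length(ct), 0, ctNoiseSd)
      return(list(ct = decaySeries(tRep, ct, "ct", repId)))
    }

    if (kind == "chx") {
      ## state after stimulation, then zero synthesis (translation blocked:
      ## equivalent to zero transcription input into the blue stage)
      s0 <- simulateTrajectory(programPersistent(1), params, stimulationHours)
      init <- c(mrna = 0, blue = unname(s0@blue[1L]), red = unname(s0@red[1L]))
    } else {
      init <- c(mrna = 0, blue = 0, red = redInit)
    }
    silent <- transcriptionProgram(numeric(0), numeric(0), numeric(0))
    traj <- simulateTrajectory(silent, params, sampleTimes, init = init)

    out <- list()
    if (kind == "chx") {
      out$blue_mfi <- mfiSeries(traj@blue, "blue")
      out$red_mfi <- mfiSeries(traj@red, "red")
    } else {
      out$red_mfi <- mfiSeries(traj@red, "red")
    }

    if (noisy && kind == "chx") {
      ## percent positive needs per-cell spread and a detection threshold
      thr <- stats::qnorm(0.999, noise@autofluorescenceMean,
                          noise@autofluorescenceSd)
      mult <- rlnormMean1(nCells, rateCv)
      pct <- function(trueAmounts, channel) {
        p <- vapply(trueAmounts, function(amt) {
          meas <- .measureChannel(mult * amt, noise, channel)
          100 * mean(meas > thr[[channel]])
        }, numeric(1))
        decaySeries(sampleTimes, p, "percent_positive", rep(1L, nt))
      }
      out$blue_pct <- pct(traj@blue, "blue")
      out$red_pct <- pct(traj@red, "red")
    }
    out
  })
}
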