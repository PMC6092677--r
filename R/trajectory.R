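#' Single-cell Timer trajectory
#'
#' Time course of mRNA (optional), blue-form and red-form protein amounts in
#' one cell, produced by [simulateTrajectory()].
#'
#' @slot times hours.
#' @slot mrna mRNA amounts (length 0 when the mRNA stage is lumped).
#' @slot blue,red protein amounts.
#' @export
setClass("CellTrajectory",
  slots = c(times = "numeric", mrna = "numeric", blue = "numeric", red = "numeric")
)

setValidity("CellTrajectory", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (length(object@blue) != n || length(object@red) != n) {
    msgs <- c(msgs, "times, blue and red must have equal length")
  }
  if (length(object@mrna) && length(object@mrna) != n) {
    msgs <- c(msgs, "mrna must be empty or of the same length as times")
  }
  tol <- -1e-9
  if (any(object@blue < tol) || any(object@red < tol) ||
      (length(object@mrna) && any(object@mrna < tol))) {
    msgs <- c(msgs, "amounts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CellTrajectory", function(object) {
  cat(sprintf(
    "CellTrajectory: %d time points over [%g, %g] h%s\n",
    length(object@times), min(object@times), max(object@times),
    if (length(object@mrna)) ", explicit mRNA stage" else ""
  ))
  invisible(object)
})

## Convolution of an exponential input q * exp(-lam * tau) with first-order
## removal at rate delta, zero initial condition:
##   solution of y' = q e^(-lam tau) - delta y, y(0) = 0.
## lam = 0 gives the constant-input response. Vectorised over tau.
.convExp <- function(q, lam, delta, tau) {
  if (q == 0) return(numeric(length(tau)))
  if (abs(delta - lam) < 1e-12 * max(abs(delta), abs(lam), 1)) {
    q * tau * exp(-delta * tau)
  } else {
    q * (exp(-lam * tau) - exp(-delta * tau)) / (delta - lam)
  }
}

## Exact propagation of state (mrna, blue, red) across one interval of
## constant transcription rate s. tau is a vector of elapsed times; returns a
## length(tau) x 3 matrix. The linear cascade is expanded over distinct
## exponentials (validity of TimerKineticParams guarantees distinct rates).
.propagateSegment <- function(state, s, params, tau) {
  r <- kineticRates(params)
  out <- matrix(0, nrow = length(tau), ncol = 3L,
                dimnames = list(NULL, c("mrna", "blue", "red")))

  if (isTRUE(params@includeMrnaStage)) {
    ## mRNA: synthesis s, decay kM.
    mEq <- s / r[["kM"]]
    mCoef <- c(mEq, state[["mrna"]] - mEq)      # on exp(0), exp(-kM tau)
    mLam <- c(0, r[["kM"]])
    out[, "mrna"] <- mCoef[1L] + mCoef[2L] * exp(-mLam[2L] * tau)
    ## blue driven by a * mrna(tau), itself an exponential sum.
    bIn <- r[["a"]] * mCoef                     # input coefficients
    bCoef <- bIn / (r[["kB"]] - mLam)           # particular-solution weights
    bLam <- mLam
  } else {
    ## mRNA lumped into synthesis: blue input is s * a, constant.
    bCoef <- s * r[["a"]] / r[["kB"]]
    bLam <- 0
  }
  bCoef <- c(bCoef, state[["blue"]] - sum(bCoef))
  bLam <- c(bLam, r[["kB"]])
  out[, "blue"] <- as.vector(exp(-outer(tau, bLam)) %*% bCoef)

  ## red driven by m * blue(tau): convolve each exponential term.
  red <- state[["red"]] * exp(-r[["dR"]] * tau)
  for (j in seq_along(bCoef)) {
    red <- red + .convExp(r[["m"]] * bCoef[j], bLam[j], r[["dR"]], tau)
  }
  out[, "red"] <- red
  ## clamp tiny negative round-off
  out[out < 0 & out > -1e-9] <- 0
  out
}

#' Simulate a single-cell Timer trajectory
#'
#' Solves the linear reporter cascade
#' \deqn{dB/dt = s(t)\,a - k_B B, \qquad dR/dt = m B - \delta_R R}
#' (optionally preceded by an explicit mRNA stage
#' \eqn{dM/dt = s(t) - k_M M}, with blue synthesis \eqn{a M}) by the exact
#' piecewise closed form, where \eqn{s(t)} is the piecewise-constant
#' transcription program. Under persistent transcription the cell approaches
#' the balanced steady state \eqn{B^* = s a / k_B},
#' \eqn{R^* = m B^* / \delta_R}; with `maturationFraction = 1` the
#' steady-state red/blue ratio equals the ratio of the red to the blue
#' half-life.
#'
#' @param program a [TranscriptionProgram-class].
#' @param params a [TimerKineticParams-class].
#' @param times sorted, non-negative evaluation grid (hours).
#' @param init named numeric initial state `c(mrna=, blue=, red=)` at time 0;
#'   default all zero.
#' @return A [CellTrajectory-class].
#' @examples
#' traj <- simulateTrajectory(programPersistent(), timerKineticParams(),
#'                            times = seq(0, 48, by = 4))
#' @export
simulateTrajectory <- function(program, params, times,
                               init = c(mrna = 0, blue = 0, red = 0)) {
  stopifnot(methods::is(program, "TranscriptionProgram"),
            methods::is(params, "TimerKineticParams"))
  methods::validObject(program)
  methods::validObject(params)
  if (length(times) == 0L) stop("empty time grid")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative")
  }
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  full <- c(mrna = 0, blue = 0, red = 0)
  if (is.null(names(init)) || !all(names(init) %in% names(full))) {
    stop("init must be named with a subset of mrna, blue, red")
  }
  full[names(init)] <- unname(init)
  if (any(full < 0)) stop("initial state must be non-negative")

  tMax <- max(times)
  seg <- program@segments
  anchors <- sort(unique(c(0, pmin(seg$start, tMax), pmin(seg$end, tMax), tMax)))
  anchors <- anchors[anchors >= 0 & anchors <= tMax]

  out <- matrix(0, nrow = length(times), ncol = 3L,
                dimnames = list(NULL, c("mrna", "blue", "red")))
  state <- full
  if (any(times == 0)) {
    out[times == 0, ] <- matrix(state, nrow = sum(times == 0), ncol = 3L,
                                byrow = TRUE)
  }
  for (i in seq_len(max(length(anchors) - 1L, 0L))) {
    a <- anchors[i]; b <- anchors[i + 1L]
    s <- transcriptionRate(program, (a + b) / 2)
    inside <- which(times > a & times <= b)
    if (length(inside)) {
      out[inside, ] <- .propagateSegment(state, s, params, times[inside] - a)
    }
    state <- .propagateSegment(state, s, params, b - a)[1L, ]
  }

  methods::new("CellTrajectory",
    times = as.numeric(times),
    mrna = if (isTRUE(params@includeMrnaStage)) unname(out[, "mrna"]) else numeric(0),
    blue = unname(out[, "blue"]),
    red = unname(out[, "red"])
  )
}

#' Steady state under constant transcription
#'
#' @param rate transcription rate (units per hour).
#' @inheritParams simulateTrajectory
#' @return Named vector `c(mrna, blue, red)` of the asymptotic state.
#' @export
steadyState <- function(rate, params) {
  stopifnot(methods::is(params, "TimerKineticParams"), rate >= 0)
  r <- kineticRates(params)
  if (isTRUE(params@includeMrnaStage)) {
    m0 <- rate / r[["kM"]]
    b0 <- r[["a"]] * m0 / r[["kB"]]
  } else {
    m0 <- 0
    b0 <- rate * r[["a"]] / r[["kB"]]
  }
  c(mrna = m0, blue = b0, red = r[["m"]] * b0 / r[["dR"]])
}
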