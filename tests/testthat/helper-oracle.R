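# Independent numerical oracle for the reporter cascade: integrates the same
# ODE system with deSolve at tight tolerances. Kept free of the closed-form
# code path it checks.
odeOracle <- function(program, params, times, init = c(mrna = 0, blue = 0, red = 0)) {
  r <- kineticRates(params)
  withMrna <- isTRUE(params@includeMrnaStage)
  deriv <- function(t, y, parms) {
    s <- transcriptionRate(program, t)
    if (withMrna) {
      dM <- s - r[["kM"]] * y[1]
      dB <- r[["a"]] * y[1] - r[["kB"]] * y[2]
      dR <- r[["m"]] * y[2] - r[["dR"]] * y[3]
      list(c(dM, dB, dR))
    } else {
      dB <- s * r[["a"]] - r[["kB"]] * y[1]
      dR <- r[["m"]] * y[1] - r[["dR"]] * y[2]
      list(c(dB, dR))
    }
  }
  y0 <- if (withMrna) init else init[c("blue", "red")]
  ## force integration steps at the program's rate discontinuities
  brk <- sort(unique(c(times, with(program@segments, c(start, pmin(end, max(times)))))))
  brk <- brk[brk >= min(times) & brk <= max(times)]
  tt <- sort(unique(c(0, times, brk)))
  out <- deSolve::ode(y = unname(y0), times = tt, func = deriv, parms = NULL,
                      rtol = 1e-11, atol = 1e-13)
  idx <- match(times, out[, 1L])
  if (withMrna) {
    list(mrna = out[idx, 2L], blue = out[idx, 3L], red = out[idx, 4L])
  } else {
    list(blue = out[idx, 2L], red = out[idx, 3L])
  }
}

# Random-but-distinct kinetic parameters for property tests.
randomParams <- function(includeMrnaStage = FALSE) {
  repeat {
    p <- try(timerKineticParams(
      mrnaHalflife = stats::runif(1, 0.5, 3),
      blueLossHalflife = stats::runif(1, 2, 8),
      maturationFraction = stats::runif(1, 0.4, 1),
      redHalflife = stats::runif(1, 50, 200),
      translationRate = stats::runif(1, 0.5, 2),
      includeMrnaStage = includeMrnaStage
    ), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

randomProgram <- function() {
  switch(sample.int(4L, 1L),
    programPersistent(stats::runif(1, 0.3, 3)),
    programNewOnset(stats::runif(1, 0, 20), stats::runif(1, 0.3, 3)),
    programArrested(stats::runif(1, 5, 40), stats::runif(1, 0.3, 3)),
    programIntermittent(stats::runif(1, 6, 30), stats::runif(1, 0.1, 0.9),
                        stats::runif(1, 0.3, 3), horizon = 200)
  )
}

silentProgram <- function() transcriptionProgram(numeric(0), numeric(0), numeric(0))

relErr <- function(x, y, floor = 1e-9) {
  max(abs(x - y) / pmax(abs(y), floor))
}
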