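test_that("parameter and program validity rejects pathological inputs", {
  expect_error(timerKineticParams(blueLossHalflife = -1), "half-lives")
  expect_error(timerKineticParams(maturationFraction = 0), "maturationFraction")
  expect_error(timerKineticParams(blueLossHalflife = 10, redHalflife = 10),
               "pairwise distinct")
  expect_error(transcriptionProgram(0, 10, -1), "rates")
  expect_error(transcriptionProgram(c(0, 5), c(8, 10), c(1, 1)), "overlap")
  p <- timerKineticParams()
  expect_error(simulateTrajectory(programPersistent(), p, numeric(0)), "empty")
  expect_error(simulateTrajectory(programPersistent(), p, c(3, 1)), "sorted")
  expect_error(simulateTrajectory(programPersistent(), p, -1), "non-negative")
})

test_that("zero transcription from a zero state stays at zero", {
  tr <- simulateTrajectory(silentProgram(), timerKineticParams(), seq(0, 48, 4))
  expect_true(all(tr@blue == 0))
  expect_true(all(tr@red == 0))
})

test_that("persistent transcription reaches the balanced steady state", {
  p <- timerKineticParams()
  ss <- steadyState(1, p)
  # steady red/blue ratio equals redHalflife / blueLossHalflife (= 122/4.1)
  expect_equal(ss[["red"]] / ss[["blue"]], 122 / 4.1, tolerance = 1e-12)
  tr <- simulateTrajectory(programPersistent(1), p, 5000)
  expect_equal(tr@blue, ss[["blue"]], tolerance = 1e-8)
  expect_equal(tr@red, ss[["red"]], tolerance = 1e-8)
})

test_that("blue halves every blue half-life once transcription is arrested", {
  p <- timerKineticParams()
  tr <- simulateTrajectory(programArrested(24), p, c(24, 24 + 4.1, 24 + 8.2))
  expect_equal(tr@blue[2] / tr@blue[1], 0.5, tolerance = 1e-10)
  expect_equal(tr@blue[3] / tr@blue[1], 0.25, tolerance = 1e-10)
})

test_that("closed form agrees with the numerical ODE oracle on random cases", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    withMrna <- i %% 4 == 0
    p <- randomParams(includeMrnaStage = withMrna)
    prog <- randomProgram()
    times <- sort(stats::runif(15, 0, 80))
    tr <- simulateTrajectory(prog, p, times)
    or <- odeOracle(prog, p, times)
    worst <- max(worst, relErr(tr@blue, or$blue, floor = 1e-6),
                 relErr(tr@red, or$red, floor = 1e-6))
  }
  expect_lt(worst, 1e-8)
})

test_that("maturation is unidirectional and conserves mass", {
  p <- timerKineticParams()
  # red cannot appear before blue production has started
  tr <- simulateTrajectory(programNewOnset(10), p, seq(0, 30, 0.5))
  expect_true(all(tr@red[tr@times <= 10] == 0))
  first_blue <- min(tr@times[tr@blue > 0])
  first_red <- min(tr@times[tr@red > 0])
  expect_gte(first_red, first_blue)
  # with maturationFraction 1 and negligible red decay, every lost blue unit
  # shows up as red
  slow <- timerKineticParams(redHalflife = 1e12)
  tr2 <- simulateTrajectory(silentProgram(), slow, c(0, 200),
                            init = c(blue = 1, red = 0))
  expect_equal(tr2@red[2], 1 - tr2@blue[2], tolerance = 1e-8)
  # with partial maturation only that fraction arrives in red
  part <- timerKineticParams(maturationFraction = 0.6, redHalflife = 1e12)
  tr3 <- simulateTrajectory(silentProgram(), part, c(0, 200),
                            init = c(blue = 1, red = 0))
  expect_equal(tr3@red[2], 0.6, tolerance = 1e-8)
})

test_that("with zero transcription blue decays; pure red decays monotonically", {
  p <- timerKineticParams()
  # blue always decays once synthesis stops ...
  tr <- simulateTrajectory(silentProgram(), p, seq(0, 48, 2),
                           init = c(blue = 5, red = 5))
  expect_true(all(diff(tr@blue) < 0))
  # ... while red can only decay monotonically once the blue pool is gone
  wo <- simulateTrajectory(silentProgram(), p, seq(0, 48, 2),
                           init = c(blue = 0, red = 5))
  expect_true(all(diff(wo@red) < 0))
})

test_that("translation blockade: red transiently rises while blue decays", {
  dec <- simulateDecayExperiment("chx", sampleTimes = seq(0, 8, 1))
  blue <- dec$blue_mfi@values
  red <- dec$red_mfi@values
  expect_true(all(diff(blue) < 0))
  expect_true(all(diff(red)[1:4] > 0)) # accumulation of maturing protein
})

test_that("decay experiment rejects unknown kinds and grids without 0", {
  expect_error(simulateDecayExperiment("boil", sampleTimes = c(0, 1)))
  expect_error(simulateDecayExperiment("chx", sampleTimes = c(1, 2)), "include 0")
})

test_that("explicit mRNA stage delays blue onset", {
  pM <- timerKineticParams(includeMrnaStage = TRUE)
  pL <- timerKineticParams()
  t <- c(0, 0.25, 0.5, 1)
  trM <- simulateTrajectory(programPersistent(1), pM, t)
  trL <- simulateTrajectory(programPersistent(1), pL, t)
  expect_true(all(trM@blue[-1] < trL@blue[-1]))
  expect_equal(length(trM@mrna), length(t))
})

test_that("population simulation is reproducible and validates inputs", {
  mix <- list(mixtureComponent(programPersistent(), onsetAge = c(10, 50)))
  s1 <- simulatePopulation(mix, nCells = 150, sampleTime = 5, seed = 77)
  s2 <- simulatePopulation(mix, nCells = 150, sampleTime = 5, seed = 77)
  expect_identical(eventTable(s1), eventTable(s2))
  expect_identical(controlTable(s1), controlTable(s2))
  s3 <- simulatePopulation(mix, nCells = 150, sampleTime = 5, seed = 78)
  expect_false(identical(eventTable(s1), eventTable(s3)))
  expect_error(simulatePopulation(list(), nCells = 10, sampleTime = 0), "empty")
  expect_error(simulatePopulation(mix, nCells = 0, sampleTime = 0), "nCells")
})

test_that("a zero-rate mixture yields the control false-positive rate", {
  q <- 0.99
  s <- simulatePopulation(list(mixtureComponent(silentProgram())),
                          nCells = 5000, sampleTime = 0, seed = 5)
  thr <- deriveThresholds(s, quantile = q)
  frac <- nPositive(gateTimerPositive(s, thr)) / 5000
  # two independent channels, each exceeded with probability ~(1 - q)
  expect_lt(abs(frac - 2 * (1 - q)), 0.012)
})

test_that("long-run mean angle decreases as transcription duty cycle rises", {
  p <- timerKineticParams()
  ss <- steadyState(1, p)
  meanAngle <- function(duty) {
    prog <- programIntermittent(12, duty, rate = 1, horizon = 2400)
    tt <- seq(1200, 1212, length.out = 121)
    tr <- simulateTrajectory(prog, p, tt)
    mean(timerAngle(tr@blue / ss[["blue"]], tr@red / ss[["red"]]))
  }
  angles <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9), meanAngle, numeric(1))
  expect_true(all(diff(angles) < 0))
})
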