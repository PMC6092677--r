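makeControl <- function(n = 200, blue = 0, red = 0) {
  data.frame(blue = rep(blue, length.out = n), red = rep(red, length.out = n))
}

test_that("thresholds are control quantiles with a sort oracle", {
  expect_s4_class(deriveThresholds(makeControl()), "ChannelThresholds")
  # all-zero control -> zero thresholds
  thr0 <- deriveThresholds(makeControl())
  expect_identical(c(thr0@blue, thr0@red), c(0, 0))
  # brute-force order-statistic oracle on random draws
  set.seed(11)
  ctrl <- data.frame(blue = rnorm(10000, 100, 25), red = rnorm(10000, 80, 20))
  thr <- deriveThresholds(ctrl, quantile = 0.999)
  expect_identical(thr@blue, sort(ctrl$blue)[ceiling(0.999 * 10000)])
  expect_identical(thr@red, sort(ctrl$red)[ceiling(0.999 * 10000)])
  # monotone in the quantile
  lo <- deriveThresholds(ctrl, quantile = 0.99)
  expect_lte(lo@blue, thr@blue)
  expect_lte(lo@red, thr@red)
  # preconditions
  expect_error(deriveThresholds(makeControl(50)), "at least 100")
  expect_error(deriveThresholds(ctrl, quantile = 0.4), "quantile")
  expect_error(deriveThresholds(ctrl, quantile = 1), "quantile")
})

test_that("gating is strict OR-exceedance of the thresholds", {
  ctrl <- makeControl(200, blue = 10, red = 20) # constant control
  thr <- deriveThresholds(ctrl)
  frame <- data.frame(
    blue = c(100, 5, 10, 10.0001, 0),
    red = c(0, 10, 20, 20, 25)
  )
  g <- gateTimerPositive(frame, thr)
  # above in one channel; below both; exactly at threshold (tie -> negative)
  expect_identical(eventTable(g)$positive, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(nPositive(g), 3L)
})

test_that("a known expressor fraction is recovered by gating", {
  mix <- list(
    mixtureComponent(programPersistent(), weight = 0.3, onsetAge = 300),
    mixtureComponent(silentProgram(), weight = 0.7)
  )
  s <- simulatePopulation(mix, nCells = 4000, sampleTime = 0, seed = 21)
  g <- gateTimerPositive(s, deriveThresholds(s))
  frac <- nPositive(g) / 4000
  expect_lt(abs(frac - 0.30), 0.02)
})

test_that("angle and intensity anchors are exact", {
  expect_equal(timerAngle(1, 0), 0)
  expect_equal(timerAngle(0, 1), 90)
  expect_equal(timerAngle(1, 1), 45)
  expect_equal(timerAngle(1, sqrt(3)), 60, tolerance = 1e-12)
  expect_equal(timerIntensity(1, 1), sqrt(2))
  expect_true(is.na(timerAngle(0, 0)))
  expect_error(timerAngle(-1, 0), ">= 0")
})

test_that("angle is scale-invariant and strictly increasing in red/blue", {
  nb <- runif(50, 0.01, 1); nr <- runif(50, 0.01, 1)
  expect_equal(timerAngle(3 * nb, 3 * nr), timerAngle(nb, nr))
  expect_equal(timerIntensity(3 * nb, 3 * nr), 3 * timerIntensity(nb, nr))
  ratios <- seq(0, 8, by = 0.25)
  ang <- timerAngle(rep(1, length(ratios)), ratios)
  expect_true(all(diff(ang) > 0))
})

test_that("transform normalises by the positive-event reference quantile", {
  ctrl <- makeControl()
  thr <- deriveThresholds(ctrl) # zero thresholds
  set.seed(3)
  frame <- data.frame(blue = runif(400, 0.1, 5), red = runif(400, 0.1, 8))
  tf <- timerTransform(gateTimerPositive(frame, thr), normQuantile = 0.975)
  d <- eventTable(tf)
  refB <- sort(frame$blue)[ceiling(0.975 * 400)]
  expect_equal(tf@reference[["blue"]], refB)
  expect_equal(d$nblue, pmin(1, frame$blue / refB))
  expect_true(all(d$timer_angle >= 0 & d$timer_angle <= 90))
  # idempotence: already-normalised data with reference 1 passes through
  norm1 <- data.frame(blue = c(d$nblue, 1), red = c(d$nred, 1))
  tf2 <- timerTransform(gateTimerPositive(norm1, thr), normQuantile = 1)
  expect_equal(eventTable(tf2)$nblue, norm1$blue)
  expect_equal(eventTable(tf2)$nred, norm1$red)
})

test_that("degenerate normalisation reference fails loudly", {
  ctrl <- makeControl(200, blue = 10, red = 10)
  thr <- deriveThresholds(ctrl)
  # positives gated only through red; blue never exceeds its threshold
  frame <- data.frame(blue = rep(4, 50), red = seq(20, 40, length.out = 50))
  expect_error(timerTransform(gateTimerPositive(frame, thr)), "degenerate")
  # an external batch reference rescues the sample
  tf <- timerTransform(gateTimerPositive(frame, thr),
                       reference = c(blue = 100, red = 35))
  expect_true(all(eventTable(tf)$timer_angle == 90))
})

test_that("homogeneous persistent steady state maps to 45 degrees exactly", {
  s <- simulatePopulation(
    list(mixtureComponent(programPersistent(), onsetAge = 2000)),
    nCells = 500, noise = NULL, sampleTime = 0, seed = 7
  )
  tf <- timerTransform(gateTimerPositive(s, deriveThresholds(s)))
  ang <- eventTable(tf)$timer_angle[eventTable(tf)$positive]
  expect_equal(length(ang), 500L)
  expect_equal(ang, rep(45, 500), tolerance = 1e-9)
})

test_that("transform requires positive events and a sane quantile", {
  ctrl <- makeControl(200, blue = 10, red = 10)
  thr <- deriveThresholds(ctrl)
  allNeg <- data.frame(blue = rep(1, 10), red = rep(1, 10))
  expect_error(timerTransform(gateTimerPositive(allNeg, thr)), "no Timer-positive")
  some <- data.frame(blue = 20:40, red = 20:40)
  expect_error(timerTransform(gateTimerPositive(some, thr), normQuantile = 0),
               "normQuantile")
})

test_that("event CSV round trip preserves the channels", {
  s <- simulatePopulation(programPersistent(), nCells = 120, sampleTime = 24,
                          seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEventsCsv(s, path)
  back <- readFlowCsv(path)
  expect_equal(back$blue, eventTable(s)$blue)
  expect_equal(back$red, eventTable(s)$red)
  expect_error(readFlowCsv(path, blue = "Nope"), "not found")
})
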