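test_that("locus anchors and boundaries match the interval definitions", {
  expect_equal(as.character(classifyLocus(c(0, 15, 30, 45, 60, 75, 90))),
               c("New", "NPt", "Persistent", "Persistent", "Persistent",
                 "PAt", "Arrested"))
  # Persistent boundaries are inclusive, transitional areas open
  eps <- 1e-9
  expect_equal(as.character(classifyLocus(c(30 - eps, 60 + eps))),
               c("NPt", "PAt"))
  # tolerance band widens the New / Arrested loci
  expect_equal(as.character(classifyLocus(c(2, 88), tolerance = 3)),
               c("New", "Arrested"))
  expect_error(classifyLocus(91), "\\[0, 90\\]")
  expect_error(classifyLocus(45, tolerance = 20), "tolerance")
})

test_that("the five loci partition [0, 90] exhaustively and exclusively", {
  grid <- seq(0, 90, by = 0.01)
  lab <- classifyLocus(grid)
  expect_false(anyNA(lab))
  # counts agree with the interval lengths of the partition
  expect_identical(sum(lab == "New"), sum(grid <= 0))
  expect_identical(sum(lab == "NPt"), sum(grid > 0 & grid < 30))
  expect_identical(sum(lab == "Persistent"), sum(grid >= 30 & grid <= 60))
  expect_identical(sum(lab == "PAt"), sum(grid > 60 & grid < 90))
  expect_identical(sum(lab == "Arrested"), sum(grid >= 90))
})

# events with prescribed normalised coordinates: thresholds 0, reference 1
eventsFromAngles <- function(angles, markers = NULL) {
  nb <- cos(angles * pi / 180)
  nr <- sin(angles * pi / 180)
  frame <- data.frame(blue = c(nb, 1), red = c(nr, 1))
  if (!is.null(markers)) {
    for (nm in names(markers)) frame[[nm]] <- c(markers[[nm]], 0)
  }
  thr <- deriveThresholds(data.frame(blue = numeric(200), red = numeric(200)))
  timerTransform(gateTimerPositive(frame, thr), normQuantile = 1)
}

test_that("sample summaries match brute-force per-event counts", {
  set.seed(31)
  angles <- runif(400, 0, 90)
  sm <- summarizeSample(eventsFromAngles(angles))
  counts <- table(classifyLocus(c(angles, 45)))
  expect_equal(unname(locusFractions(sm)), as.numeric(counts) / 401)
  expect_equal(sum(locusFractions(sm)), 1, tolerance = 1e-12)
  expect_equal(sm@meanAngle, mean(c(angles, 45)), tolerance = 1e-9)
  expect_true(qcIncluded(sm))
})

test_that("samples with too few positive events are QC-excluded", {
  sm <- summarizeSample(eventsFromAngles(runif(18))) # 18 + anchor = 19 events
  expect_identical(sm@nPositive, 19L)
  expect_false(qcIncluded(sm))
  expect_true(qcIncluded(summarizeSample(eventsFromAngles(runif(19)))))
  # configurable threshold
  expect_true(qcIncluded(summarizeSample(eventsFromAngles(runif(18)), minN = 10)))
})

test_that("a uniform 45-degree sample is pure Persistent", {
  sm <- summarizeSample(eventsFromAngles(rep(45, 50)))
  expect_equal(locusFractions(sm)[["Persistent"]], 1)
  expect_equal(sm@meanAngle, 45)
})

test_that("locus fractions are invariant to event order and rescaling", {
  set.seed(32)
  base <- data.frame(blue = rlnorm(300, 5, 1), red = rlnorm(300, 5, 1))
  ctrl <- data.frame(blue = rnorm(200, 5, 1), red = rnorm(200, 5, 1))
  run <- function(frame, control) {
    tf <- timerTransform(gateTimerPositive(frame, deriveThresholds(control)))
    locusFractions(summarizeSample(tf))
  }
  ref <- run(base, ctrl)
  perm <- base[sample.int(300), ]
  expect_equal(run(perm, ctrl), ref)
  # the same positive rescaling of sample and control changes nothing
  expect_equal(run(base * 7.3, ctrl * 7.3), ref)
})

test_that("simulated cohorts land in the expected loci", {
  # newly induced cells (onset within the last 4 h) are enriched in New+NPt
  coh <- simulatePopulation(
    list(mixtureComponent(programNewOnset(0), onsetAge = c(0, 4))),
    nCells = 2000, sampleTime = 0, seed = 3
  )
  tf <- timerTransform(gateTimerPositive(coh, deriveThresholds(coh)))
  fr <- locusFractions(summarizeSample(tf))
  expect_gt(fr[["New"]] + fr[["NPt"]], 0.5)
  expect_lt(fr[["Arrested"]], 0.05)

  # an arrested population sampled many blue half-lives after arrest is
  # essentially pure Arrested (batch reference from a persistent sample)
  pers <- simulatePopulation(
    list(mixtureComponent(programPersistent(), onsetAge = 300)),
    nCells = 2000, sampleTime = 0, seed = 9
  )
  tfP <- timerTransform(gateTimerPositive(pers, deriveThresholds(pers)))
  arr <- simulatePopulation(
    list(mixtureComponent(programArrested(48), onsetAge = 108)), # 60 h post-arrest
    nCells = 2000, sampleTime = 0, seed = 4
  )
  tfA <- timerTransform(gateTimerPositive(arr, deriveThresholds(arr)),
                        reference = tfP@reference)
  expect_gte(locusFractions(summarizeSample(tfA))[["Arrested"]], 0.99)
})

test_that("angle KDE is a proper density on [0, 90]", {
  # concentrated data: single peak at 45, unit mass
  d <- angleDensity(rep(45, 100) + rnorm(100, 0, 0.1), bandwidth = 1)
  expect_equal(d@grid[which.max(d@density)], 45, tolerance = 0.5)
  integral <- sum(diff(d@grid) * (head(d@density, -1) + tail(d@density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  # uniform angles: approximately flat at 1/90 per degree
  set.seed(41)
  u <- angleDensity(runif(1e5, 0, 90))
  interior <- u@density[u@grid > 5 & u@grid < 85]
  expect_lt(max(abs(interior - 1 / 90)) / (1 / 90), 0.1)
  # mass piled at the 0 boundary: no leakage, still integrates to 1
  set.seed(42)
  edge <- angleDensity(pmin(abs(rnorm(5000, 0, 2)), 90))
  integral <- sum(diff(edge@grid) * (head(edge@density, -1) + tail(edge@density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_gt(edge@density[1], edge@density[length(edge@density)])
  expect_error(angleDensity(45), "at least 2")
  expect_error(angleDensity(c(45, 95)), "\\[0, 90\\]")
})

test_that("marker profiles by locus recover programmed step functions", {
  angles <- c(rep(0, 30), rep(15, 30), rep(45, 30), rep(75, 30), rep(90, 30))
  step <- c(New = 10, NPt = 20, Persistent = 40, PAt = 5, Arrested = 1)
  lab <- as.character(classifyLocus(angles))
  ev <- eventsFromAngles(angles, markers = list(
    mk_step = unname(step[lab]),
    mk_const = rep(3, length(angles))
  ))
  prof <- locusMarkerProfile(ev, c("mk_step", "mk_const"))
  # the transform appends one 45-degree anchor event with marker value 0
  expected <- step
  expected["Persistent"] <- (30 * 40 + 0) / 31
  expect_equal(prof$profile[, "mk_step"], expected)
  expect_equal(unname(prof$profile[, "mk_const"]), c(3, 3, 3 * 30 / 31, 3, 3))
  expect_length(prof$missingLoci, 0)
  expect_s3_class(prof$clustering, "hclust")
  expect_error(locusMarkerProfile(ev, "absent"), "unknown marker")
})

test_that("empty loci are flagged missing, not imputed, and do not break clustering", {
  ev <- eventsFromAngles(rep(45, 40), markers = list(m1 = rnorm(40), m2 = rnorm(40)))
  prof <- locusMarkerProfile(ev, c("m1", "m2"))
  expect_setequal(prof$missingLoci, c("New", "NPt", "PAt", "Arrested"))
  expect_true(all(is.na(prof$profile["New", ])))
  expect_s3_class(prof$clustering, "hclust")
  expect_false(anyNA(prof$clustering$height))
})
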