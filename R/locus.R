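#' @rdname classifyLocus
#' @export
locusLevels <- c("New", "NPt", "Persistent", "PAt", "Arrested")

#' Classify Timer-Angle into transcription-dynamics loci
#'
#' The five loci partition the angle range: New at 0 degrees (transcription
#' just initiated, no matured red yet), Persistent on [30, 60] (balanced
#' blue/red around 45 degrees, frequent transcription), Arrested at 90
#' (blue lost, transcription stopped), and the transitional NPt (between New
#' and Persistent) and PAt (between Persistent and Arrested) areas.
#' Persistent is closed and the transitional areas open, which makes the
#' partition exhaustive and mutually exclusive. Because measured angles are
#' continuous, the exact-0/90 loci admit a `tolerance` band (default 0: New
#' means the red signal was at or below threshold, so the angle is exactly
#' 0; likewise Arrested).
#'
#' @param angle angles in degrees, in [0, 90] (NA passes through).
#' @param tolerance band width in degrees for the New and Arrested loci,
#'   in [0, 15).
#' @return Factor with levels `locusLevels`.
#' @examples
#' classifyLocus(c(0, 15, 45, 75, 90))
#' @export
classifyLocus <- function(angle, tolerance = 0) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L,
            tolerance >= 0, tolerance < 15)
  ok <- !is.na(angle)
  if (any(angle[ok] < 0 | angle[ok] > 90)) {
    stop("angles must lie in [0, 90]")
  }
  lab <- rep(NA_character_, length(angle))
  a <- angle[ok]
  lab[ok] <- ifelse(a <= tolerance, "New",
             ifelse(a >= 90 - tolerance, "Arrested",
             ifelse(a >= 30 & a <= 60, "Persistent",
             ifelse(a < 30, "NPt", "PAt"))))
  factor(lab, levels = locusLevels)
}

#' Per-sample locus summary
#'
#' Locus fractions (over Timer-positive events), mean Timer-Angle, mean raw
#' blue/red fluorescence of positive events, and the quality-control flag:
#' samples with fewer than `minN` positive events are marked excluded
#' (default 20).
#'
#' @slot fractions named numeric over the five loci (sums to 1; NA when no
#'   positive events).
#' @slot nPositive number of Timer-positive events.
#' @slot meanAngle,meanBlue,meanRed summary statistics of positive events.
#' @slot qcIncluded logical; FALSE when `nPositive < minN`.
#' @slot minN threshold used.
#' @slot tolerance locus tolerance used.
#' @slot sampleId sample label.
#' @export
setClass("LocusSummary",
  slots = c(fractions = "numeric", nPositive = "integer",
            meanAngle = "numeric", meanBlue = "numeric", meanRed = "numeric",
            qcIncluded = "logical", minN = "integer", tolerance = "numeric",
            sampleId = "character")
)

setValidity("LocusSummary", function(object) {
  msgs <- character()
  f <- object@fractions
  if (!identical(names(f), locusLevels)) {
    msgs <- c(msgs, "fractions must be named by the five loci")
  }
  if (!anyNA(f)) {
    if (any(f < 0) || any(f > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
    if (abs(sum(f) - 1) > 1e-12) msgs <- c(msgs, "fractions must sum to 1")
  }
  if (object@qcIncluded && object@nPositive < object@minN) {
    msgs <- c(msgs, "qcIncluded must be FALSE when nPositive < minN")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "LocusSummary", function(object) {
  cat(sprintf("LocusSummary '%s': %d Timer-positive events%s\n",
    object@sampleId, object@nPositive,
    if (object@qcIncluded) "" else sprintf(" [QC-excluded, min_n=%d]", object@minN)))
  if (!anyNA(object@fractions)) {
    cat("  fractions:",
        paste(sprintf("%s %.3f", names(object@fractions), object@fractions),
              collapse = ", "), "\n")
    cat(sprintf("  mean angle %.2f deg, mean blue %.4g, mean red %.4g\n",
      object@meanAngle, object@meanBlue, object@meanRed))
  }
  invisible(object)
})

#' @rdname LocusSummary-class
#' @param x a `LocusSummary`.
#' @export
locusFractions <- function(x) {
  stopifnot(methods::is(x, "LocusSummary"))
  x@fractions
}

#' @rdname LocusSummary-class
#' @export
qcIncluded <- function(x) {
  stopifnot(methods::is(x, "LocusSummary"))
  x@qcIncluded
}

#' Summarise a transformed sample by Timer locus
#'
#' @param events a transformed [TimerEvents-class].
#' @param minN minimum number of Timer-positive events for the sample to be
#'   included in downstream statistics (default 20).
#' @param tolerance passed to [classifyLocus()].
#' @return A [LocusSummary-class]. With zero positive events the summary is
#'   returned with `qcIncluded = FALSE` and NA statistics rather than an
#'   error.
#' @export
summarizeSample <- function(events, minN = 20L, tolerance = 0) {
  stopifnot(methods::is(events, "TimerEvents"))
  if (!isTRUE(events@transformed)) stop("events must be transformed first")
  minN <- as.integer(minN)
  df <- events@data
  pos <- df[df$positive, , drop = FALSE]
  n <- nrow(pos)
  if (n == 0L) {
    fr <- stats::setNames(rep(NA_real_, 5L), locusLevels)
    return(methods::new("LocusSummary",
      fractions = fr, nPositive = 0L,
      meanAngle = NA_real_, meanBlue = NA_real_, meanRed = NA_real_,
      qcIncluded = FALSE, minN = minN, tolerance = tolerance,
      sampleId = events@sampleId))
  }
  loci <- classifyLocus(pos$timer_angle, tolerance)
  fr <- as.numeric(table(loci)) / n
  names(fr) <- locusLevels
  methods::new("LocusSummary",
    fractions = fr, nPositive = as.integer(n),
    meanAngle = mean(pos$timer_angle),
    meanBlue = mean(pos$blue), meanRed = mean(pos$red),
    qcIncluded = n >= minN, minN = minN, tolerance = tolerance,
    sampleId = events@sampleId
  )
}

#' Bounded-support Timer-Angle density
#'
#' Gaussian kernel density of Timer-Angle values on [0, 90] degrees with
#' boundary reflection at both ends, renormalised to integrate to 1 on the
#' support.
#'
#' @slot grid angle grid (degrees).
#' @slot density density values (per degree).
#' @slot bandwidth kernel bandwidth (degrees).
#' @slot n number of angles used.
#' @export
setClass("AngleDensity",
  slots = c(grid = "numeric", density = "numeric",
            bandwidth = "numeric", n = "integer")
)

setValidity("AngleDensity", function(object) {
  msgs <- character()
  if (length(object@grid) != length(object@density)) {
    msgs <- c(msgs, "grid and density must have equal length")
  }
  if (any(object@density < 0)) msgs <- c(msgs, "density must be >= 0")
  if (abs(trapezoidIntegral(object@grid, object@density) - 1) > 1e-6) {
    msgs <- c(msgs, "density must integrate to 1 on [0, 90]")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AngleDensity", function(object) {
  cat(sprintf("AngleDensity: n = %d, bandwidth %.3g deg, %d grid points\n",
    object@n, object@bandwidth, length(object@grid)))
  invisible(object)
})

#' Kernel-density estimate of Timer-Angle values
#'
#' Gaussian kernel with reflection at the 0 and 90 degree boundaries
#' (each data point contributes kernels centred at `a`, `-a` and
#' `180 - a`), evaluated on an equispaced grid and renormalised by its
#' trapezoidal integral so no probability mass leaks outside the support.
#' Default bandwidth by Silverman's rule of thumb on the raw angles.
#'
#' @param angles at least 2 angles in [0, 90] degrees.
#' @param bandwidth kernel bandwidth in degrees; default Silverman.
#' @param gridSize number of grid points.
#' @return An [AngleDensity-class].
#' @export
angleDensity <- function(angles, bandwidth = NULL, gridSize = 512L) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2L) stop("need at least 2 angles")
  if (any(angles < 0 | angles > 90)) stop("angles must lie in [0, 90]")
  bw <- bandwidth %||% stats::bw.nrd0(angles)
  if (!is.finite(bw) || bw <= 0) bw <- 0.5  # degenerate spread fallback
  aug <- c(angles, -angles, 180 - angles)
  d <- stats::density(aug, bw = bw, from = 0, to = 90, n = gridSize)
  y <- 3 * d$y  # the augmented sample has 3n points; fold the reflections in
  y <- y / trapezoidIntegral(d$x, y)
  methods::new("AngleDensity",
    grid = d$x, density = y, bandwidth = bw, n = length(angles)
  )
}

#' Marker expression profile by Timer locus
#'
#' Mean fluorescence of each marker within each locus, as used for heatmap
#' profiling of surface proteins against transcription dynamics. Loci with
#' no events are reported as NA rows and flagged, never imputed; the
#' optional complete-linkage hierarchical clustering of markers is computed
#' on the complete loci only.
#'
#' @param events a transformed [TimerEvents-class] whose data carries the
#'   marker columns.
#' @param markers character vector of marker column names.
#' @param tolerance passed to [classifyLocus()].
#' @param standardise scale each marker column to zero mean and unit
#'   variance across loci (for heatmap display).
#' @param cluster compute a complete-linkage `hclust` of the markers.
#' @return List with `profile` (locus x marker matrix), `missingLoci`,
#'   and `clustering` (an `hclust` or NULL).
#' @export
locusMarkerProfile <- function(events, markers, tolerance = 0,
                               standardise = FALSE, cluster = TRUE) {
  stopifnot(methods::is(events, "TimerEvents"))
  if (!isTRUE(events@transformed)) stop("events must be transformed first")
  df <- events@data
  missing <- setdiff(markers, names(df))
  if (length(missing)) {
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  }
  pos <- df[df$positive, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no Timer-positive events")
  loci <- classifyLocus(pos$timer_angle, tolerance)
  prof <- matrix(NA_real_, nrow = length(locusLevels), ncol = length(markers),
                 dimnames = list(locusLevels, markers))
  for (lv in locusLevels) {
    sel <- loci == lv
    if (any(sel)) {
      prof[lv, ] <- vapply(markers, function(m) mean(pos[[m]][sel]), numeric(1))
    }
  }
  missingLoci <- locusLevels[rowSums(is.na(prof)) == length(markers)]
  if (standardise) {
    keep <- !rownames(prof) %in% missingLoci
    prof[keep, ] <- scale(prof[keep, , drop = FALSE])
  }
  clustering <- NULL
  if (cluster && length(markers) >= 2L) {
    complete <- prof[!rownames(prof) %in% missingLoci, , drop = FALSE]
    clustering <- stats::hclust(stats::dist(t(complete)), method = "complete")
  }
  list(profile = prof, missingLoci = missingLoci, clustering = clustering)
}
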