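#' Group comparison with QC audit
#'
#' Result of [compareGroups()]: the test applied, its statistic and p-value,
#' the pairwise table when a post hoc procedure is involved, and the audit
#' trail of samples excluded by the positive-event quality-control rule
#' before any testing took place.
#'
#' @slot metric name of the compared metric.
#' @slot test test identifier.
#' @slot groupSizes named integer vector of per-group sizes after QC.
#' @slot statistic named numeric (test statistic).
#' @slot pValue overall p-value.
#' @slot pairwise data.frame of pairwise comparisons (possibly empty):
#'   columns `comparison`, `estimate`, `statistic`, `p`, `p_adj`.
#' @slot excluded data.frame of excluded samples: `sample`, `group`,
#'   `n_positive`, `rule`.
#' @export
setClass("GroupComparison",
  slots = c(metric = "character", test = "character",
            groupSizes = "integer", statistic = "numeric", pValue = "numeric",
            pairwise = "data.frame", excluded = "data.frame")
)

setValidity("GroupComparison", function(object) {
  msgs <- character()
  pw <- object@pairwise
  if (nrow(pw) && all(c("p", "p_adj") %in% names(pw))) {
    ok <- is.na(pw$p) | is.na(pw$p_adj) | pw$p_adj >= pw$p - 1e-12
    if (!all(ok)) msgs <- c(msgs, "adjusted p-values must be >= raw p-values")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of '%s' by %s\n", object@metric, object@test))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(object@groupSizes),
                                 object@groupSizes), collapse = ", "), "\n")
  cat(sprintf("  %s = %.4g, p = %.4g\n",
    names(object@statistic)[1L] %||% "stat", object@statistic[1L], object@pValue))
  if (nrow(object@excluded)) {
    cat(sprintf("  %d sample(s) QC-excluded (%s)\n", nrow(object@excluded),
      object@excluded$rule[1L]))
  }
  if (nrow(object@pairwise)) {
    cat(sprintf("  %d pairwise comparison(s)\n", nrow(object@pairwise)))
  }
  invisible(object)
})

#' @rdname GroupComparison-class
#' @param x a `GroupComparison`.
#' @export
excludedSamples <- function(x) {
  stopifnot(methods::is(x, "GroupComparison"))
  x@excluded
}

#' @rdname GroupComparison-class
#' @export
pairwiseResults <- function(x) {
  stopifnot(methods::is(x, "GroupComparison"))
  x@pairwise
}

## Dunn's post hoc z-tests on the joint ranks after a Kruskal-Wallis test,
## with tie correction; two-sided p-values adjusted by `method`.
.dunnTest <- function(values, groups, method = "bonferroni") {
  groups <- droplevels(as.factor(groups))
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanRanks <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lv <- levels(groups)
  combs <- utils::combn(lv, 2L)
  res <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (meanRanks[[i]] - meanRanks[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(
    comparison = paste(combs[1L, ], combs[2L, ], sep = " - "),
    estimate = NA_real_,
    statistic = res["z", ],
    p = res["p", ],
    p_adj = stats::p.adjust(res["p", ], method = method),
    row.names = NULL
  )
}

#' Compare a metric between groups with QC exclusion
#'
#' Applies the field's standard group-comparison conventions to per-sample
#' metrics (locus fractions, mean Timer-Angle, MFI, ...): samples failing
#' the positive-event rule (`n_positive < minN`) are excluded and audited
#' *before* any testing, then the chosen test runs on the remainder.
#'
#' Tests: `mann_whitney` (two groups, [stats::wilcox.test()]),
#' `kruskal_wallis_dunn` ([stats::kruskal.test()] with Dunn's multiple
#' comparisons), `t_test`, `anova_tukey` (one-way ANOVA with Tukey's honest
#' significant difference), and `two_way_anova_sidak` (two-way ANOVA with
#' Sidak-adjusted pairwise t-tests within each level of `group2`).
#'
#' @param data data.frame with one row per sample.
#' @param value name of the metric column.
#' @param group name of the grouping column.
#' @param test test identifier (see Details).
#' @param minN QC rule: minimum Timer-positive events per sample
#'   (default 20).
#' @param nPositiveCol name of the positive-count column; if absent from
#'   `data`, no QC exclusion is applied.
#' @param sampleCol name of the sample-identifier column (used in the
#'   audit), if present.
#' @param group2 second factor for `two_way_anova_sidak`.
#' @param padjMethod adjustment for Dunn's comparisons (default
#'   `"bonferroni"`).
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(data, value, group,
                          test = c("mann_whitney", "kruskal_wallis_dunn",
                                   "t_test", "anova_tukey",
                                   "two_way_anova_sidak"),
                          minN = 20L, nPositiveCol = "n_positive",
                          sampleCol = "sample", group2 = NULL,
                          padjMethod = "bonferroni") {
  test <- match.arg(test)
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  minN <- as.integer(minN)

  ## QC audit before testing
  allGroups <- unique(as.character(data[[group]]))
  if (nPositiveCol %in% names(data)) {
    bad <- data[[nPositiveCol]] < minN
    excluded <- data.frame(
      sample = if (sampleCol %in% names(data)) {
        as.character(data[[sampleCol]][bad])
      } else paste0("row", which(bad)),
      group = as.character(data[[group]][bad]),
      n_positive = data[[nPositiveCol]][bad],
      rule = rep(sprintf("min_n=%d", minN), sum(bad)),
      row.names = NULL
    )
    data <- data[!bad, , drop = FALSE]
  } else {
    excluded <- data.frame(sample = character(), group = character(),
                           n_positive = integer(), rule = character())
  }
  gone <- setdiff(allGroups, unique(as.character(data[[group]])))
  if (length(gone)) {
    stop("all samples of group(s) ", paste(gone, collapse = ", "),
         " were excluded by the QC rule min_n=", minN)
  }

  v <- data[[value]]
  g <- droplevels(as.factor(data[[group]]))
  sizes <- vapply(split(v, g), length, integer(1))
  if (length(levels(g)) < 2L) stop("need at least 2 groups")

  empty <- data.frame(comparison = character(), estimate = numeric(),
                      statistic = numeric(), p = numeric(), p_adj = numeric())
  if (test == "mann_whitney") {
    if (length(levels(g)) != 2L) stop("mann_whitney requires exactly 2 groups")
    ## exact when sample sizes permit and no ties; ties fall back to the
    ## continuity-corrected normal approximation (with a warning we silence)
    ht <- suppressWarnings(stats::wilcox.test(v ~ g))
    stat <- c(W = unname(ht$statistic)); p <- ht$p.value; pw <- empty
  } else if (test == "t_test") {
    if (length(levels(g)) != 2L) stop("t_test requires exactly 2 groups")
    ht <- stats::t.test(v ~ g)
    stat <- c(t = unname(ht$statistic)); p <- ht$p.value; pw <- empty
  } else if (test == "kruskal_wallis_dunn") {
    ht <- stats::kruskal.test(v, g)
    stat <- c(chi_squared = unname(ht$statistic)); p <- ht$p.value
    pw <- .dunnTest(v, g, method = padjMethod)
  } else if (test == "anova_tukey") {
    dd <- data.frame(v = v, g = g)
    fit <- stats::aov(v ~ g, data = dd)
    tab <- summary(fit)[[1L]]
    stat <- c(F = tab[["F value"]][1L]); p <- tab[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(
      comparison = gsub("-", " - ", rownames(tk), fixed = TRUE),
      estimate = tk[, "diff"], statistic = NA_real_,
      p = tk[, "p adj"], p_adj = tk[, "p adj"], row.names = NULL
    )
  } else { # two_way_anova_sidak
    if (is.null(group2) || !group2 %in% names(data)) {
      stop("two_way_anova_sidak requires a 'group2' column name")
    }
    g2 <- droplevels(as.factor(data[[group2]]))
    dd <- data.frame(v = v, g = g, g2 = g2)
    fit <- stats::aov(v ~ g * g2, data = dd)
    tab <- summary(fit)[[1L]]
    stat <- c(F_interaction = tab[["F value"]][3L])
    p <- tab[["Pr(>F)"]][1L]
    rows <- list()
    for (lev2 in levels(g2)) {
      sub <- dd[dd$g2 == lev2, , drop = FALSE]
      for (pr in utils::combn(levels(g), 2L, simplify = FALSE)) {
        a <- sub$v[sub$g == pr[1L]]; b <- sub$v[sub$g == pr[2L]]
        if (length(a) >= 2L && length(b) >= 2L) {
          ht <- stats::t.test(a, b)
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = sprintf("%s - %s @ %s", pr[1L], pr[2L], lev2),
            estimate = unname(diff(rev(ht$estimate))),
            statistic = unname(ht$statistic), p = ht$p.value,
            p_adj = NA_real_
          )
        }
      }
    }
    pw <- do.call(rbind, rows) %||% empty
    if (nrow(pw)) pw$p_adj <- 1 - (1 - pw$p)^nrow(pw)  # Sidak
  }

  methods::new("GroupComparison",
    metric = value, test = test,
    groupSizes = sizes, statistic = stat, pValue = p,
    pairwise = pw, excluded = excluded
  )
}

#' Turn locus summaries into a tidy metric table
#'
#' One row per sample with the locus fractions, mean angle, MFIs and the
#' positive-event count, ready for [compareGroups()] or CSV export.
#'
#' @param summaries list of [LocusSummary-class] objects.
#' @return data.frame with columns `sample`, `n_positive`, `qc_included`,
#'   one column per locus fraction, `mean_angle`, `mean_blue`, `mean_red`.
#' @export
locusSummaryTable <- function(summaries) {
  if (methods::is(summaries, "LocusSummary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    fr <- as.list(s@fractions)
    names(fr) <- paste0("frac_", tolower(names(fr)))
    cbind(
      data.frame(sample = s@sampleId, n_positive = s@nPositive,
                 qc_included = s@qcIncluded),
      as.data.frame(fr),
      data.frame(mean_angle = s@meanAngle, mean_blue = s@meanBlue,
                 mean_red = s@meanRed)
    )
  })
  do.call(rbind, rows)
}
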