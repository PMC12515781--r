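# Cohort-level summaries, normality-gated testing, effect flags, daily profile.

#' Median and interquartile range of a per-subject metric
#'
#' Quantiles use the linear-interpolation convention (R type 7).
#'
#' @param x numeric values (NAs dropped).
#' @return named vector \code{n}, \code{median}, \code{q1}, \code{q3},
#'   \code{iqr}.
#' @examples
#' summarizeMetric(1:5)  # median 3, IQR 2
#' @export
summarizeMetric <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Normality-gated two-sample test
#'
#' With \code{test = "auto"}, each sample is screened with the Shapiro--Wilk
#' test at alpha = 0.05; if both look normal an unequal-variance (Welch)
#' unpaired t test is used, otherwise the Mann--Whitney U test. The
#' Mann--Whitney branch uses the exact null distribution for small tie-free
#' samples and the tie-corrected normal approximation (with continuity
#' correction) otherwise. Two-sided p-values throughout; significance at
#' alpha = 0.05. Samples identical everywhere yield p = 1 with a warning.
#'
#' @param a,b numeric per-subject metric values (>= 3 each for \code{"auto"}).
#' @param test \code{"auto"}, \code{"t"}, or \code{"mann_whitney"}.
#' @param alpha significance level.
#' @return list: \code{test} used, \code{statistic}, \code{pValue},
#'   \code{significant}, \code{nA}, \code{nB}.
#' @examples
#' chooseAndTest(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")  # exact p 0.1
#' @export
chooseAndTest <- function(a, b, test = c("auto", "t", "mann_whitney"),
                          alpha = 0.05) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both samples; p = 1")
    return(list(test = "mann_whitney", statistic = NA_real_, pValue = 1,
                significant = FALSE, nA = length(a), nB = length(b)))
  }
  if (test == "auto") {
    stopifnot(length(a) >= 3, length(b) >= 3)
    looksNormal <- function(x) {
      if (length(unique(x)) < 3) return(FALSE)
      stats::shapiro.test(x)$p.value > 0.05
    }
    test <- if (looksNormal(a) && looksNormal(b)) "t" else "mann_whitney"
  }
  if (test == "t") {
    ht <- stats::t.test(a, b, var.equal = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  }
  p <- ht$p.value
  list(test = test, statistic = unname(ht$statistic), pValue = p,
       significant = is.finite(p) && p < alpha, nA = length(a),
       nB = length(b))
}

#' Effect-size flag from the absolute standardized mean difference
#'
#' Bands mirror the report footnote convention: |SMD| > 0.2 moderate,
#' > 0.5 large.
#'
#' @param a,b numeric per-subject metric values.
#' @return list: \code{absSmd}, \code{band} in
#'   \code{c("none", "moderate", "large")}.
#' @export
effectFlags <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  s <- abs(smd(a, b, kind = "continuous"))
  band <- if (s > 0.5) "large" else if (s > 0.2) "moderate" else "none"
  list(absSmd = s, band = band)
}

#' Ambulatory daily glucose profile
#'
#' Pools all readings of all subjects and days by 5-minute clock-time bin and
#' returns per-bin median, 5th and 95th percentiles -- the day-overlaid
#' percentile profile used to compare cohorts' daily shapes.
#'
#' @param x a \linkS4class{CgmCohort} or a list of \linkS4class{CgmTrace}.
#' @param interval bin width in minutes (must match the trace grid).
#' @return data.frame with one row per clock bin: \code{bin}, \code{clock}
#'   ("HH:MM"), \code{n}, \code{median}, \code{p5}, \code{p95} (bins with no
#'   readings carry NAs).
#' @export
dailyProfile <- function(x, interval = 5) {
  trs <- if (is(x, "CgmCohort")) x@traces else x
  stopifnot(length(trs) >= 1)
  secs <- unlist(lapply(trs, function(tr) as.numeric(tr@time) %% 86400))
  g <- unlist(lapply(trs, function(tr) tr@glucose))
  nBins <- as.integer(86400 / (interval * 60))
  bin <- factor(floor(secs / (interval * 60)), levels = 0:(nBins - 1L))
  byBin <- split(g, bin)
  qs <- vapply(byBin, function(v) {
    if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE, type = 7),
      length(v))
  }, numeric(4))
  mins <- (0:(nBins - 1L)) * interval
  data.frame(bin = 0:(nBins - 1L),
             clock = sprintf("%02d:%02d", mins %/% 60, mins %% 60),
             n = as.integer(qs[4, ]), median = qs[2, ], p5 = qs[1, ],
             p95 = qs[3, ], stringsAsFactors = FALSE, row.names = NULL)
}

# Report row order and labels: the 14-metric panel.
.reportMetrics <- function() {
  c(mean_glucose = "Mean glucose level (mg/dL)",
    tir = "TIR (%) [70-180 mg/dL]",
    titr = "TITR (%) [70-140 mg/dL]",
    tar = "TAR (%) [>180 mg/dL]",
    tbr = "TBR (%) [<70 mg/dL]",
    cv = "CV",
    n_l1_events = "L1 hypoglycaemic events",
    mean_l1_duration = "L1 hypoglycaemic events duration (min)",
    n_l2_events = "L2 hypoglycaemic events",
    mean_l2_duration = "L2 hypoglycaemic events duration (min)",
    n_hyper_events = "Hyperglycaemic events",
    mean_hyper_duration = "Hyperglycaemic events duration (min)",
    time_l1 = "Time in L1 hypoglycaemic range (%)",
    time_l2 = "Time in L2 hypoglycaemic range (%)")
}

#' Build the cohort-comparison report
#'
#' For each of the 14 panel metrics and each period (overall/day/night),
#' summarizes every cohort as median (IQR), flags the effect size of the
#' reference cohort versus each comparator (|SMD| > 0.2 / > 0.5), and runs the
#' normality-gated two-group test reference-vs-comparator. Mean event
#' durations are summarized over subjects that experienced at least one event.
#' Raw p-values are reported without multiple-testing correction.
#'
#' @param panels stacked per-subject panels from
#'   \code{\link{cohortMetricPanel}} for all cohorts.
#' @param reference reference cohort label (default \code{"RYGB"}).
#' @param comparators comparator labels in display order.
#' @return a \linkS4class{CohortReport}.
#' @export
buildReport <- function(panels, reference = "RYGB",
                        comparators = c("HEALTHY", "T1D")) {
  need <- c(reference, comparators)
  have <- unique(panels$cohort)
  if (!all(need %in% have))
    stop("missing cohort(s): ", paste(setdiff(need, have), collapse = ", "))
  metrics <- names(.reportMetrics())
  periods <- c("overall", "day", "night")
  sumRows <- list(); testRows <- list()
  for (m in metrics) for (per in periods) {
    vals <- lapply(need, function(co)
      panels[panels$cohort == co & panels$period == per, m])
    names(vals) <- need
    for (co in need) {
      v <- vals[[co]][!is.na(vals[[co]])]
      s <- if (length(v)) summarizeMetric(v)
           else c(n = 0, median = NA_real_, iqr = NA_real_)
      sumRows[[length(sumRows) + 1L]] <-
        data.frame(metric = m, period = per, cohort = co, n = s[["n"]],
                   median = s[["median"]], iqr = s[["iqr"]],
                   stringsAsFactors = FALSE)
    }
    for (co in comparators) {
      va <- vals[[reference]][!is.na(vals[[reference]])]
      vb <- vals[[co]][!is.na(vals[[co]])]
      if (length(va) >= 3 && length(vb) >= 3) {
        tt <- suppressWarnings(chooseAndTest(va, vb))
        ef <- effectFlags(va, vb)
        testRows[[length(testRows) + 1L]] <-
          data.frame(metric = m, period = per, comparison = co,
                     test = tt$test, statistic = tt$statistic,
                     p_value = tt$pValue, significant = tt$significant,
                     abs_smd = ef$absSmd, band = ef$band,
                     stringsAsFactors = FALSE)
      } else {
        testRows[[length(testRows) + 1L]] <-
          data.frame(metric = m, period = per, comparison = co,
                     test = NA_character_, statistic = NA_real_,
                     p_value = NA_real_, significant = NA,
                     abs_smd = NA_real_, band = NA_character_,
                     stringsAsFactors = FALSE)
      }
    }
  }
  new("CohortReport", summary = do.call(rbind, sumRows),
      tests = do.call(rbind, testRows), metrics = metrics,
      reference = reference)
}

#' Formatted median (IQR) report table
#'
#' One row per metric; per period and cohort a "median (IQR)" cell, with
#' \code{*}/\code{**} marking |SMD| > 0.2 / > 0.5 of the reference versus the
#' first comparator and \code{+}/\code{++} versus the second.
#'
#' @param report a \linkS4class{CohortReport}.
#' @return data.frame of formatted cells, one column per period x cohort.
#' @export
reportTable <- function(report) {
  s <- report@summary; tst <- report@tests
  cohortsIn <- unique(s$cohort)
  comparators <- setdiff(cohortsIn, report@reference)
  flagChar <- c(none = "", moderate = "*", large = "**")
  flagChar2 <- c(none = "", moderate = "+", large = "++")
  out <- data.frame(metric = unname(.reportMetrics()[report@metrics]),
                    stringsAsFactors = FALSE)
  for (per in c("overall", "day", "night")) for (co in cohortsIn) {
    cells <- vapply(report@metrics, function(m) {
      r <- s[s$metric == m & s$period == per & s$cohort == co, ]
      flag <- ""
      if (co %in% comparators) {
        t <- tst[tst$metric == m & tst$period == per & tst$comparison == co, ]
        if (nrow(t) && !is.na(t$band))
          flag <- if (co == comparators[1]) flagChar[[t$band]]
                  else flagChar2[[t$band]]
      }
      if (is.na(r$median)) "-" else sprintf("%.1f (%.1f)%s", r$median,
                                            r$iqr, flag)
    }, character(1))
    out[[paste(per, co, sep = ".")]] <- unname(cells)
  }
  out
}

#' Render a report table as a markdown pipe table
#'
#' @param report a \linkS4class{CohortReport}.
#' @return character vector of markdown lines.
#' @export
reportMarkdown <- function(report) {
  tab <- reportTable(report)
  hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(hdr, sep, body,
    "",
    paste("Note: values are median (IQR); * and ** mark |SMD| > 0.2 and",
          "> 0.5 vs the first comparator, + and ++ vs the second;",
          "p-values are unadjusted."))
}
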