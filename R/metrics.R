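# Consensus glycaemic metric panel: band times, variability, events, GMI.

#' Time-in-band percentages
#'
#' Percentages of non-missing readings falling in the consensus glucose bands.
#' Band boundaries are closed below and open above so the partition is exact:
#' TIR \eqn{70 \le g \le 180}, TITR \eqn{70 \le g \le 140}, TAR \eqn{g > 180},
#' TBR \eqn{g < 70}, level-1 range \eqn{54 \le g < 70}, level-2 range
#' \eqn{g < 54}. By construction \code{tir + tar + tbr = 100} and
#' \code{tbr = time_l1 + time_l2}.
#'
#' @param glucose numeric glucose readings (mg/dL) or a \linkS4class{CgmTrace}.
#' @param config a \linkS4class{MetricConfig}.
#' @return named numeric vector \code{tir}, \code{titr}, \code{tar},
#'   \code{tbr}, \code{time_l1}, \code{time_l2} (percent).
#' @examples
#' bandTimes(c(100, 100, 200, 60, 50))
#' @export
bandTimes <- function(glucose, config = metricConfig()) {
  if (is(glucose, "CgmTrace")) glucose <- glucose@glucose
  glucose <- glucose[!is.na(glucose)]
  if (length(glucose) == 0)
    stopWithClass("cgmNoDataError", "no data in period")
  pct <- function(x) 100 * mean(x)
  c(tir = pct(glucose >= config@tirBand[1] & glucose <= config@tirBand[2]),
    titr = pct(glucose >= config@titrBand[1] & glucose <= config@titrBand[2]),
    tar = pct(glucose > config@tirBand[2]),
    tbr = pct(glucose < config@l1Threshold),
    time_l1 = pct(glucose >= config@l2Threshold & glucose < config@l1Threshold),
    time_l2 = pct(glucose < config@l2Threshold))
}

#' Coefficient of variation of glucose
#'
#' Sample standard deviation divided by the mean, in percent.
#'
#' @param glucose numeric readings or a \linkS4class{CgmTrace}.
#' @return CV in percent.
#' @export
cvPercent <- function(glucose) {
  if (is(glucose, "CgmTrace")) glucose <- glucose@glucose
  glucose <- glucose[!is.na(glucose)]
  if (length(glucose) < 2)
    stopWithClass("cgmNoDataError", "insufficient data: CV needs >= 2 readings")
  100 * stats::sd(glucose) / mean(glucose)
}

#' Glucose management indicator
#'
#' HbA1c-equivalent estimated from mean CGM glucose by the established linear
#' formula \eqn{GMI = 3.31 + 0.02392 \times \bar{g}} (percent).
#'
#' @param meanGlucose mean glucose in mg/dL, positive.
#' @return GMI in percent HbA1c-equivalent.
#' @examples
#' gmi(139.1)
#' @export
gmi <- function(meanGlucose) {
  if (any(!is.finite(meanGlucose)) || any(meanGlucose <= 0))
    stop("meanGlucose must be positive")
  3.31 + 0.02392 * meanGlucose
}

# Core run-scan on one gap-free segment. `beyond` flags readings strictly
# beyond the event threshold. Returns a list of c(startIdx, endIdx).
.scanRuns <- function(beyond, minEvent, minRecovery) {
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  i <- 1L
  nRun <- length(r$lengths)
  while (i <= nRun) {
    if (r$values[i] && r$lengths[i] >= minEvent) {
      s <- starts[i]; e <- ends[i]; j <- i + 1L
      # absorb recovered stretches shorter than minRecovery that are followed
      # by further beyond-threshold readings
      while (j + 1L <= nRun && !r$values[j] && r$lengths[j] < minRecovery &&
             r$values[j + 1L]) {
        e <- ends[j + 1L]
        j <- j + 2L
      }
      out[[length(out) + 1L]] <- c(s, e)
      i <- j
      if (i <= nRun && !r$values[i]) i <- i + 1L   # skip the closing recovery
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Detect contiguous glycaemic events
#'
#' An event starts at the first of at least \code{minEventPoints} (default 3)
#' consecutive readings strictly beyond the threshold -- below 70 mg/dL for
#' level-1 hypoglycaemia, below 54 for level-2, above 180 for hyperglycaemia.
#' The event ends when \code{minRecoveryPoints} consecutive readings have
#' recovered (15 min at defaults), at a data gap wider than one nominal
#' interval, or at the end of the series; the event's last reading is the last
#' beyond-threshold reading before that. Brief recoveries shorter than the
#' recovery rule are absorbed into the event. Duration is the number of
#' readings spanned times the nominal interval.
#'
#' @param trace a \linkS4class{CgmTrace} (sorted, gaps = absent slots).
#' @param kind \code{"hypo_l1"}, \code{"hypo_l2"} or \code{"hyper"}.
#' @param config a \linkS4class{MetricConfig}.
#' @return data.frame with columns \code{kind}, \code{start}, \code{end}
#'   (POSIXct of first/last in-event reading), \code{n_readings},
#'   \code{duration_min}, \code{extremum} (nadir for hypoglycaemia, peak for
#'   hyperglycaemia); zero rows when no event is found.
#' @examples
#' t0 <- as.POSIXct("2023-03-01", tz = "UTC")
#' tr <- CgmTrace("S1", t0 + 300 * (0:6), c(60, 60, 60, 72, 60, 60, 60))
#' detectEvents(tr, "hypo_l1")   # one 35-min event
#' @export
detectEvents <- function(trace, kind = c("hypo_l1", "hypo_l2", "hyper"),
                         config = metricConfig()) {
  kind <- match.arg(kind)
  g <- trace@glucose
  empty <- data.frame(kind = character(), start = as.POSIXct(character(),
                                                             tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_readings = integer(), duration_min = numeric(),
                      extremum = numeric(), stringsAsFactors = FALSE)
  if (length(g) == 0) return(empty)
  beyond <- switch(kind,
                   hypo_l1 = g < config@l1Threshold,
                   hypo_l2 = g < config@l2Threshold,
                   hyper = g > config@hyperThreshold)
  step <- trace@interval * 60
  gapAfter <- c(diff(as.numeric(trace@time)) > step + 0.5, TRUE)
  segEnd <- which(gapAfter)
  segStart <- c(1L, utils::head(segEnd, -1L) + 1L)
  rows <- list()
  for (s in seq_along(segStart)) {
    ix <- segStart[s]:segEnd[s]
    for (ev in .scanRuns(beyond[ix], config@minEventPoints,
                         config@minRecoveryPoints)) {
      a <- ix[ev[1]]; b <- ix[ev[2]]
      n <- b - a + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, start = trace@time[a], end = trace@time[b],
        n_readings = n, duration_min = n * trace@interval,
        extremum = if (kind == "hyper") max(g[a:b]) else min(g[a:b]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a set of detected events
#'
#' @param events data.frame from \code{\link{detectEvents}}.
#' @return list with \code{count} and \code{meanDuration} (minutes;
#'   \code{NA} when there are no events).
#' @export
eventSummary <- function(events) {
  n <- nrow(events)
  list(count = n,
       meanDuration = if (n == 0) NA_real_ else mean(events$duration_min))
}

.periodOf <- function(time) ifelse(hourOfDay(time) >= 6, "day", "night")

#' The full per-subject metric panel for overall / daytime / nighttime
#'
#' Computes, for each of the three periods, mean glucose, CV, the six
#' time-in-band percentages, GMI, and the counts and mean durations of
#' level-1/level-2 hypoglycaemic and hyperglycaemic events. Events are
#' detected once on the full windowed trace and assigned to the period
#' containing their start reading, with the full duration credited to that
#' period.
#'
#' @param trace a \linkS4class{CgmTrace}.
#' @param window an \linkS4class{AnalysisWindow} (or \code{NULL} to use the
#'   whole trace).
#' @param config a \linkS4class{MetricConfig}.
#' @return data.frame with one row per period (\code{overall}, \code{day},
#'   \code{night}) and the metric columns.
#' @export
metricPanel <- function(trace, window = NULL, config = metricConfig()) {
  parts <- splitPeriods(trace, window)
  overall <- parts$overall
  events <- list(l1 = detectEvents(overall, "hypo_l1", config),
                 l2 = detectEvents(overall, "hypo_l2", config),
                 hyper = detectEvents(overall, "hyper", config))
  if (!config@l1IncludesL2 && nrow(events$l1)) {
    # optional stricter convention: drop L1 runs whose nadir is below the L2
    # threshold (pure-L1 counting)
    events$l1 <- events$l1[events$l1$extremum >= config@l2Threshold, ,
                           drop = FALSE]
  }
  onePeriod <- function(label) {
    tr <- parts[[if (label == "overall") "overall" else label]]
    g <- tr@glucose
    if (length(g) == 0)
      stopWithClass("cgmNoDataError", paste("no data in period", label))
    bt <- bandTimes(g, config)
    evOf <- function(ev) {
      if (label != "overall" && nrow(ev))
        ev <- ev[.periodOf(ev$start) == label, , drop = FALSE]
      eventSummary(ev)
    }
    l1 <- evOf(events$l1); l2 <- evOf(events$l2); hy <- evOf(events$hyper)
    data.frame(period = label, n_readings = length(g),
               mean_glucose = mean(g),
               cv = if (length(g) >= 2) cvPercent(g) else NA_real_,
               tir = bt[["tir"]], titr = bt[["titr"]], tar = bt[["tar"]],
               tbr = bt[["tbr"]], time_l1 = bt[["time_l1"]],
               time_l2 = bt[["time_l2"]],
               n_l1_events = l1$count, mean_l1_duration = l1$meanDuration,
               n_l2_events = l2$count, mean_l2_duration = l2$meanDuration,
               n_hyper_events = hy$count, mean_hyper_duration = hy$meanDuration,
               gmi = gmi(mean(g)), stringsAsFactors = FALSE)
  }
  out <- rbind(onePeriod("overall"), onePeriod("day"), onePeriod("night"))
  rownames(out) <- NULL
  out
}

#' Metric panels for every eligible subject of a cohort
#'
#' Selects each subject's earliest eligible analysis window, computes the
#' metric panel, and stacks the results. Ineligible subjects (no window with
#' sufficient wear) are dropped and listed in the \code{ineligible} attribute.
#'
#' @param cohort a \linkS4class{CgmCohort}.
#' @param nDays,minWear window selection rules (10 days, wear >= 0.7).
#' @param config a \linkS4class{MetricConfig}.
#' @return data.frame of stacked panels with \code{subject_id} and
#'   \code{cohort} columns; attribute \code{ineligible} holds the dropped ids.
#' @export
cohortMetricPanel <- function(cohort, nDays = 10, minWear = 0.7,
                              config = metricConfig()) {
  panels <- list()
  ineligible <- character()
  for (id in names(cohort@traces)) {
    tr <- cohort@traces[[id]]
    win <- tryCatch(selectWindow(tr, nDays = nDays, minWear = minWear),
                    cgmIneligibleError = function(e) NULL)
    if (is.null(win)) {
      ineligible <- c(ineligible, id)
      next
    }
    p <- metricPanel(tr, win, config)
    p <- cbind(subject_id = id, cohort = cohort@name, p,
               stringsAsFactors = FALSE)
    panels[[id]] <- p
  }
  out <- do.call(rbind, panels)
  rownames(out) <- NULL
  attr(out, "ineligible") <- ineligible
  out
}

#' All detected events for every eligible subject of a cohort
#'
#' @inheritParams cohortMetricPanel
#' @return data.frame of events with \code{subject_id} and \code{cohort}.
#' @export
cohortEvents <- function(cohort, nDays = 10, minWear = 0.7,
                         config = metricConfig()) {
  rows <- list()
  for (id in names(cohort@traces)) {
    tr <- cohort@traces[[id]]
    win <- tryCatch(selectWindow(tr, nDays = nDays, minWear = minWear),
                    cgmIneligibleError = function(e) NULL)
    if (is.null(win)) next
    wt <- windowTrace(tr, win)
    ev <- rbind(detectEvents(wt, "hypo_l1", config),
                detectEvents(wt, "hypo_l2", config),
                detectEvents(wt, "hyper", config))
    if (nrow(ev))
      rows[[id]] <- cbind(subject_id = id, cohort = cohort@name, ev,
                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), cohort = character(),
                      kind = character(), start = as.POSIXct(character(),
                                                             tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_readings = integer(), duration_min = numeric(),
                      extremum = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
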