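# Wear-time accounting, analysis-window selection, day/night stratification.

#' Sensor wear fraction over a calendar window
#'
#' Observed readings inside the window divided by the number of nominal grid
#' slots the window contains. A window outside the trace span yields 0.
#'
#' @param trace a \linkS4class{CgmTrace}.
#' @param start first calendar date of the window (\code{Date} or coercible).
#' @param nDays number of consecutive days.
#' @return wear fraction in [0, 1].
#' @examples
#' tr <- CgmTrace("S1", as.POSIXct("2023-03-01", tz = "UTC") + 300 * (0:2879),
#'                rep(100, 2880))
#' wearFraction(tr, "2023-03-01", 10)  # 1.0
#' @export
wearFraction <- function(trace, start, nDays = 10) {
  stopifnot(is(trace, "CgmTrace"), nDays >= 1)
  start <- as.Date(start)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  t1 <- t0 + nDays * 86400
  observed <- sum(trace@time >= t0 & trace@time < t1)
  expected <- nDays * 1440 / trace@interval
  min(1, observed / expected)
}

#' Select the earliest eligible consecutive-day analysis window
#'
#' Scans candidate start dates from the first calendar day of the trace and
#' returns the earliest \code{nDays}-day window whose wear fraction meets
#' \code{minWear} (inclusive at the threshold). If no window qualifies, an
#' error of class \code{cgmIneligibleError} is signalled carrying the best
#' achievable wear fraction (\code{bestWear}) and its start date
#' (\code{bestStart}).
#'
#' @param trace a \linkS4class{CgmTrace}.
#' @param nDays window length in days (default 10).
#' @param minWear minimum wear fraction (default 0.7).
#' @return an \linkS4class{AnalysisWindow}.
#' @export
selectWindow <- function(trace, nDays = 10, minWear = 0.7) {
  stopifnot(is(trace, "CgmTrace"))
  if (length(trace) == 0)
    stopWithClass("cgmIneligibleError", "empty trace", bestWear = 0,
                  bestStart = as.Date(NA))
  dates <- as.Date(trace@time, tz = "UTC")
  d0 <- min(dates); d1 <- max(dates)
  spanDays <- as.integer(d1 - d0) + 1L
  expected <- nDays * 1440 / trace@interval
  if (spanDays < nDays) {
    bw <- length(trace) / expected
    stopWithClass("cgmIneligibleError",
                  sprintf("trace spans %d days; %d required", spanDays, nDays),
                  bestWear = min(1, bw), bestStart = d0)
  }
  allDays <- seq(d0, d1, by = "day")
  counts <- as.numeric(table(factor(dates, levels = as.character(allDays))))
  # rolling nDays-day sums over consecutive calendar days
  cs <- cumsum(c(0, counts))
  nStart <- length(allDays) - nDays + 1L
  wear <- (cs[(nDays + 1):(nDays + nStart)] - cs[1:nStart]) / expected
  ok <- which(wear >= minWear)
  if (length(ok) == 0) {
    best <- which.max(wear)
    stopWithClass("cgmIneligibleError",
                  sprintf("no %d-day window reaches wear %.2f (best %.3f)",
                          nDays, minWear, wear[best]),
                  bestWear = wear[best], bestStart = allDays[best])
  }
  new("AnalysisWindow", start = allDays[ok[1]], nDays = as.integer(nDays),
      wearFraction = min(1, wear[ok[1]]))
}

#' Restrict a trace to an analysis window
#'
#' @param trace a \linkS4class{CgmTrace}.
#' @param window an \linkS4class{AnalysisWindow}.
#' @return a \linkS4class{CgmTrace} containing only readings inside the window.
#' @export
windowTrace <- function(trace, window) {
  t0 <- as.POSIXct(paste(window@start, "00:00:00"), tz = "UTC")
  t1 <- t0 + window@nDays * 86400
  keep <- trace@time >= t0 & trace@time < t1
  CgmTrace(trace@subjectId, trace@time[keep], trace@glucose[keep],
           interval = trace@interval)
}

#' Split a windowed trace into overall / daytime / nighttime reading sets
#'
#' Daytime is the half-open clock interval [06:00, 24:00), nighttime
#' [00:00, 06:00); the two partition the full day exactly, so
#' \code{length(day) + length(night) == length(overall)} always holds.
#'
#' @param trace a \linkS4class{CgmTrace}.
#' @param window optional \linkS4class{AnalysisWindow}; if supplied the trace
#'   is first restricted to it.
#' @return named list of three \linkS4class{CgmTrace}: \code{overall},
#'   \code{day}, \code{night}.
#' @export
splitPeriods <- function(trace, window = NULL) {
  if (!is.null(window)) trace <- windowTrace(trace, window)
  day <- isDaytime(trace@time)
  mk <- function(keep) CgmTrace(trace@subjectId, trace@time[keep],
                                trace@glucose[keep], interval = trace@interval)
  list(overall = trace, day = mk(day), night = mk(!day))
}
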