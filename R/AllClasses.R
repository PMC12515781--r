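#' @import methods
NULL

setOldClass(c("POSIXct", "POSIXt"))
setOldClass("Date")

#' CgmTrace: one subject's glucose time series on a nominal grid
#'
#' A \code{CgmTrace} holds the timestamped interstitial glucose readings of a
#' single subject on a nominal sampling grid (5 minutes for the devices this
#' package models). Gaps are represented by absent grid slots, never by
#' \code{NA} readings. Glucose is stored in mg/dL and must lie within the
#' reportable sensor span of 40--400 mg/dL.
#'
#' @slot subjectId opaque subject identifier.
#' @slot time \code{POSIXct} (UTC) timestamps, strictly increasing, each an
#'   integer number of nominal intervals apart from its neighbours.
#' @slot glucose numeric vector of glucose readings, mg/dL.
#' @slot interval nominal sampling interval in minutes (default 5).
#'
#' @examples
#' tr <- CgmTrace("S1", as.POSIXct("2023-03-01", tz = "UTC") + 300 * (0:11),
#'                rep(100, 12))
#' tr
#' @export
setClass("CgmTrace",
         representation(subjectId = "character", time = "POSIXct",
                        glucose = "numeric", interval = "numeric"))

setValidity("CgmTrace", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (length(object@time) != length(object@glucose))
    msg <- c(msg, "time and glucose must have equal length")
  if (length(object@interval) != 1L || object@interval <= 0)
    msg <- c(msg, "interval must be a single positive number")
  n <- length(object@time)
  if (n > 0) {
    d <- diff(as.numeric(object@time))
    if (any(d <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    step <- object@interval * 60
    if (any(abs(d / step - round(d / step)) > 1e-6))
      msg <- c(msg, "timestamp differences must be integer multiples of the nominal interval")
    g <- object@glucose
    if (any(!is.finite(g))) msg <- c(msg, "glucose must be finite")
    else if (any(g < 40 - 1e-9 | g > 400 + 1e-9))
      msg <- c(msg, "glucose must lie within the reportable span [40, 400] mg/dL")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CgmTrace
#'
#' @param subjectId subject identifier.
#' @param time POSIXct timestamps (coerced to UTC representation as given).
#' @param glucose glucose readings in mg/dL.
#' @param interval nominal interval in minutes.
#' @return a \linkS4class{CgmTrace}.
#' @export
CgmTrace <- function(subjectId, time, glucose, interval = 5) {
  new("CgmTrace", subjectId = as.character(subjectId), time = time,
      glucose = as.numeric(glucose), interval = interval)
}

#' CgmCohort: a named set of traces plus subject covariates
#'
#' @slot name cohort label, e.g. \code{"RYGB"}, \code{"T1D"}, \code{"HEALTHY"}.
#' @slot traces named list of \linkS4class{CgmTrace}, names = subject ids.
#' @slot covariates data.frame with one row per subject; must contain a
#'   \code{subject_id} column matching the trace names, and typically
#'   \code{age}, \code{sex} (1 = female, 0 = male), \code{bmi}, \code{cohort}.
#' @slot metadata free-form list (parse reports, provenance).
#' @export
setClass("CgmCohort",
         representation(name = "character", traces = "list",
                        covariates = "data.frame", metadata = "list"))

setValidity("CgmCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@traces, is, logical(1), "CgmTrace")))
    msg <- c(msg, "all traces must be CgmTrace objects")
  ids <- vapply(object@traces, function(t) t@subjectId, character(1))
  if (length(object@traces) && !identical(unname(ids), names(object@traces)))
    msg <- c(msg, "trace list names must equal the traces' subject ids")
  if (nrow(object@covariates) > 0) {
    if (!"subject_id" %in% names(object@covariates))
      msg <- c(msg, "covariates must have a subject_id column")
    else if (length(object@traces) &&
             !all(names(object@traces) %in% object@covariates$subject_id))
      msg <- c(msg, "every trace must have a covariate row")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CgmCohort
#' @param name cohort label.
#' @param traces named list of \linkS4class{CgmTrace}.
#' @param covariates per-subject covariate data.frame.
#' @param metadata optional list.
#' @return a \linkS4class{CgmCohort}.
#' @export
CgmCohort <- function(name, traces, covariates = data.frame(), metadata = list()) {
  if (is.null(names(traces)) && length(traces))
    names(traces) <- vapply(traces, function(t) t@subjectId, character(1))
  new("CgmCohort", name = name, traces = traces, covariates = covariates,
      metadata = metadata)
}

#' AnalysisWindow: a consecutive-calendar-day analysis window
#'
#' @slot start first calendar date of the window.
#' @slot nDays number of consecutive days (default 10).
#' @slot wearFraction observed readings / expected grid slots, in [0, 1].
#' @export
setClass("AnalysisWindow",
         representation(start = "Date", nDays = "integer",
                        wearFraction = "numeric"))

setValidity("AnalysisWindow", function(object) {
  msg <- character()
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (object@wearFraction < 0 || object@wearFraction > 1)
    msg <- c(msg, "wearFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MetricConfig: thresholds and rules for the glycaemic metric panel
#'
#' Defaults follow the international consensus conventions: TIR 70--180 mg/dL,
#' TITR 70--140 mg/dL, level-1 hypoglycaemia threshold 70 mg/dL, level-2
#' threshold 54 mg/dL, hyperglycaemia threshold 180 mg/dL, and events defined
#' by at least three consecutive readings beyond a threshold with three
#' consecutive recovered readings (15 min) ending an event.
#'
#' @slot tirBand,titrBand closed glucose bands, mg/dL.
#' @slot l1Threshold,l2Threshold,hyperThreshold mg/dL.
#' @slot minEventPoints consecutive beyond-threshold readings needed to start
#'   an event.
#' @slot minRecoveryPoints consecutive recovered readings that end an event.
#' @slot l1IncludesL2 logical; if \code{TRUE} (default) any run below
#'   70 mg/dL counts as a level-1 event even when it deepens below 54.
#' @export
setClass("MetricConfig",
         representation(tirBand = "numeric", titrBand = "numeric",
                        l1Threshold = "numeric", l2Threshold = "numeric",
                        hyperThreshold = "numeric", minEventPoints = "integer",
                        minRecoveryPoints = "integer", l1IncludesL2 = "logical"))

setValidity("MetricConfig", function(object) {
  msg <- character()
  if (!(object@l2Threshold < object@l1Threshold &&
        object@l1Threshold < object@hyperThreshold))
    msg <- c(msg, "thresholds must satisfy l2 < l1 < hyper")
  if (object@minEventPoints < 1L) msg <- c(msg, "minEventPoints must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MetricConfig
#' @param tirBand,titrBand closed bands in mg/dL.
#' @param l1Threshold,l2Threshold,hyperThreshold thresholds in mg/dL.
#' @param minEventPoints,minRecoveryPoints consecutive-reading rules.
#' @param l1IncludesL2 count runs that deepen below the level-2 threshold as
#'   level-1 events too.
#' @return a \linkS4class{MetricConfig}.
#' @export
metricConfig <- function(tirBand = c(70, 180), titrBand = c(70, 140),
                         l1Threshold = 70, l2Threshold = 54,
                         hyperThreshold = 180, minEventPoints = 3L,
                         minRecoveryPoints = 3L, l1IncludesL2 = TRUE) {
  new("MetricConfig", tirBand = tirBand, titrBand = titrBand,
      l1Threshold = l1Threshold, l2Threshold = l2Threshold,
      hyperThreshold = hyperThreshold,
      minEventPoints = as.integer(minEventPoints),
      minRecoveryPoints = as.integer(minRecoveryPoints),
      l1IncludesL2 = l1IncludesL2)
}

#' PropensityModel: a fitted logistic propensity model
#'
#' @slot coefficients named coefficients on the original covariate scale.
#' @slot converged logical convergence flag.
#' @slot nIterations IRLS iterations used.
#' @slot scores named vector of propensity scores in (0, 1) for all subjects.
#' @slot group named 0/1 vector (1 = reference) aligned with \code{scores}.
#' @export
setClass("PropensityModel",
         representation(coefficients = "numeric", converged = "logical",
                        nIterations = "integer", scores = "numeric",
                        group = "numeric"))

setValidity("PropensityModel", function(object) {
  if (any(object@scores <= 0 | object@scores >= 1))
    "propensity scores must lie strictly in (0, 1)" else TRUE
})

#' MatchResult: pairs produced by greedy 1:1 matching
#'
#' @slot pairs data.frame with columns \code{reference_id}, \code{matched_id},
#'   \code{distance} (logit-score scale).
#' @slot unmatchedReference ids of reference subjects left unmatched.
#' @slot caliperUsed caliper width on the logit-score scale (\code{NA} = none).
#' @export
setClass("MatchResult",
         representation(pairs = "data.frame", unmatchedReference = "character",
                        caliperUsed = "numeric"))

setValidity("MatchResult", function(object) {
  msg <- character()
  if (nrow(object@pairs) &&
      anyDuplicated(object@pairs$matched_id))
    msg <- c(msg, "matching must be 1:1 without replacement")
  if (nrow(object@pairs) && anyDuplicated(object@pairs$reference_id))
    msg <- c(msg, "each reference subject may appear in at most one pair")
  if (length(msg)) msg else TRUE
})

#' BalanceReport: standardized mean differences before/after matching
#'
#' @slot table data.frame with columns \code{covariate}, \code{kind},
#'   \code{smd_pre}, \code{smd_post}.
#' @slot maxAbsSmdAfter maximum absolute post-matching SMD.
#' @slot threshold balance threshold (0.1 by convention).
#' @slot balanced logical: \code{maxAbsSmdAfter < threshold}.
#' @export
setClass("BalanceReport",
         representation(table = "data.frame", maxAbsSmdAfter = "numeric",
                        threshold = "numeric", balanced = "logical"))

#' ArchetypeParams: generative parameters for one cohort archetype
#'
#' Parameters of the latent glucose model (circadian basal rhythm, meal
#' excursion kernels, post-meal undershoot, autoregressive physiological
#' wander, nocturnal instability), the multiplicative AR(1) sensor-noise model
#' tuned to a target mean absolute relative difference (MARD), and the gap
#' (dropout) process. Units are mg/dL for amplitudes, minutes for time
#' constants, clock hours for meal times.
#'
#' @slot name archetype label: \code{"RYGB"}, \code{"T1D"} or \code{"HEALTHY"}.
#' @slot basalMean basal glucose level, mg/dL.
#' @slot circadianAmplitude amplitude of the 24-h basal sinusoid (minimum near
#'   03:00), mg/dL.
#' @slot mealTimes mean clock hours of the daily main meals.
#' @slot mealTimeSd SD of meal-time jitter, hours.
#' @slot extraMealProb probability of an extra daytime snack per day.
#' @slot extraMealWindow clock-hour range the snack is drawn from.
#' @slot peakMedian,peakSdlog log-normal meal excursion peak height, mg/dL.
#' @slot riseMin,fallMin bi-exponential excursion time constants, minutes.
#' @slot undershootProb probability a meal is followed by a reactive
#'   undershoot.
#' @slot undershootDepthMean,undershootDepthSd truncated-normal undershoot
#'   depth, mg/dL.
#' @slot undershootDelayMin delay of the undershoot kernel after the meal,
#'   minutes.
#' @slot undershootRiseMin,undershootFallMin undershoot kernel time constants.
#' @slot wanderSd,wanderRho stationary SD (mg/dL) and lag-1 correlation of the
#'   AR(1) physiological wander.
#' @slot nocturnalSd,nocturnalRho stationary SD and lag-1 correlation of the
#'   additional nocturnal instability component (active 00:00--06:00).
#' @slot noiseRho lag-1 correlation of the multiplicative sensor noise.
#' @slot mardTarget target MARD of sensor vs latent glucose, percent.
#' @slot dropoutRate fraction of grid slots removed as wear gaps.
#' @slot dropoutBurstMean mean gap-burst length, slots.
#' @export
setClass("ArchetypeParams",
         representation(name = "character", basalMean = "numeric",
                        circadianAmplitude = "numeric", mealTimes = "numeric",
                        mealTimeSd = "numeric", extraMealProb = "numeric",
                        extraMealWindow = "numeric", peakMedian = "numeric",
                        peakSdlog = "numeric", riseMin = "numeric",
                        fallMin = "numeric", undershootProb = "numeric",
                        undershootDepthMean = "numeric",
                        undershootDepthSd = "numeric",
                        undershootDelayMin = "numeric",
                        undershootRiseMin = "numeric",
                        undershootFallMin = "numeric", wanderSd = "numeric",
                        wanderRho = "numeric", nocturnalSd = "numeric",
                        nocturnalRho = "numeric", noiseRho = "numeric",
                        mardTarget = "numeric", dropoutRate = "numeric",
                        dropoutBurstMean = "numeric"))

setValidity("ArchetypeParams", function(object) {
  msg <- character()
  if (object@basalMean <= 0) msg <- c(msg, "basalMean must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 0.3)
    msg <- c(msg, "dropoutRate must lie in [0, 0.3)")
  for (s in c("wanderRho", "nocturnalRho", "noiseRho")) {
    v <- slot(object, s)
    if (v < 0 || v >= 1) msg <- c(msg, paste(s, "must lie in [0, 1)"))
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: configuration of a three-cohort simulation
#'
#' @slot nSubjects subjects per cohort (45 by default).
#' @slot nDays recording days per subject (10 by default).
#' @slot interval grid interval, minutes.
#' @slot seed integer master seed; fixed seed implies byte-identical output.
#' @slot startDate first calendar date of every recording.
#' @slot archetypes named list of \linkS4class{ArchetypeParams} for
#'   \code{RYGB}, \code{HEALTHY}, \code{T1D}.
#' @slot scenario \code{"matched"} (identical covariate distributions, sex
#'   exactly 36 female / 9 male per cohort of 45) or \code{"confounded"}
#'   (comparison pools 4x the reference size with age shifted +8 years and
#'   BMI -2 kg/m2, for exercising the matcher).
#' @export
setClass("SimConfig",
         representation(nSubjects = "integer", nDays = "integer",
                        interval = "numeric", seed = "integer",
                        startDate = "Date", archetypes = "list",
                        scenario = "character"))

#' CgmSimulation: simulated cohorts with retained latent traces
#'
#' @slot cohorts named list of \linkS4class{CgmCohort} (sensor traces).
#' @slot latent named list of \linkS4class{CgmTrace}, the noise-free latent
#'   glucose of every simulated subject.
#' @slot config the \linkS4class{SimConfig} used.
#' @export
setClass("CgmSimulation",
         representation(cohorts = "list", latent = "list",
                        config = "SimConfig"))

#' CohortReport: the cohort-comparison report
#'
#' @slot summary long data.frame: metric, period, cohort, n, median, iqr.
#' @slot tests data.frame of pairwise test results and effect flags.
#' @slot metrics character vector of metric keys, in report row order.
#' @slot reference reference cohort label.
#' @export
setClass("CohortReport",
         representation(summary = "data.frame", tests = "data.frame",
                        metrics = "character", reference = "character"))
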