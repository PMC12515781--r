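# Frozen default generative parameters for the three cohort archetypes.
#
# The defaults were calibrated once, by coarse search, so that 45-subject,
# 10-day cohorts reproduce the cohort-median metric signatures of the three
# study populations (mean glucose, CV, TIR, hypoglycaemic event frequency,
# day/night variability asymmetry) and a sensor MARD near 9%; they are part
# of the package contract and should not be tuned per analysis.

#' Frozen archetype defaults for the three simulated cohorts
#'
#' \describe{
#'   \item{RYGB}{post-bariatric physiology with confirmed post-bariatric
#'     hypoglycaemia: near-normal basal glucose, fast tall meal excursions
#'     followed by reactive undershoots that frequently cross 70 (and at
#'     times 54) mg/dL, quiet nights.}
#'   \item{T1D}{insulin-pump-treated type 1 diabetes: elevated basal glucose,
#'     slow broad excursions, large physiological wander day and night
#'     (nocturnal instability), occasional insulin-overcorrection lows.}
#'   \item{HEALTHY}{tight glycaemic control: low-amplitude excursions, small
#'     wander, rare shallow dips below 70 mg/dL.}
#' }
#'
#' @param name \code{"RYGB"}, \code{"T1D"} or \code{"HEALTHY"}.
#' @return an \linkS4class{ArchetypeParams}.
#' @examples
#' archetypeDefaults("RYGB")
#' @export
archetypeDefaults <- function(name = c("RYGB", "T1D", "HEALTHY")) {
  name <- match.arg(name)
  base <- list(mealTimes = c(7.5, 12.5, 19), mealTimeSd = 0.6,
               extraMealProb = 0.5, extraMealWindow = c(15, 17),
               noiseRho = 0.7, mardTarget = 9, dropoutRate = 0.07,
               dropoutBurstMean = 6)
  p <- switch(name,
    RYGB = list(basalMean = 99, circadianAmplitude = 5,
                peakMedian = 75, peakSdlog = 0.30, riseMin = 18, fallMin = 38,
                undershootProb = 0.95, undershootDepthMean = 22,
                undershootDepthSd = 18, undershootDelayMin = 100,
                undershootRiseMin = 28, undershootFallMin = 45,
                wanderSd = 7, wanderRho = 0.995,
                nocturnalSd = 9, nocturnalRho = 0.995),
    T1D = list(basalMean = 122, circadianAmplitude = 6,
               peakMedian = 68, peakSdlog = 0.35, riseMin = 30, fallMin = 70,
               undershootProb = 0.30, undershootDepthMean = 55,
               undershootDepthSd = 10, undershootDelayMin = 140,
               undershootRiseMin = 25, undershootFallMin = 40,
               wanderSd = 22, wanderRho = 0.997,
               nocturnalSd = 32, nocturnalRho = 0.996),
    HEALTHY = list(basalMean = 92, circadianAmplitude = 5,
                   peakMedian = 24, peakSdlog = 0.30, riseMin = 25,
                   fallMin = 55,
                   undershootProb = 0.12, undershootDepthMean = 12,
                   undershootDepthSd = 8, undershootDelayMin = 110,
                   undershootRiseMin = 30, undershootFallMin = 55,
                   wanderSd = 5.2, wanderRho = 0.995,
                   nocturnalSd = 0, nocturnalRho = 0.995))
  do.call(new, c(list("ArchetypeParams", name = name), base, p))
}

#' Construct a simulation configuration
#'
#' @param nSubjects subjects per cohort.
#' @param nDays recording days per subject.
#' @param interval grid interval, minutes.
#' @param seed master integer seed (fans out to per-subject seeds by stable
#'   hashing of the subject id).
#' @param startDate first calendar date of every recording.
#' @param archetypes named list of \linkS4class{ArchetypeParams}.
#' @param scenario \code{"matched"} or \code{"confounded"}.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSubjects = 45, nDays = 10, interval = 5,
                      seed = 20260301, startDate = as.Date("2023-03-01"),
                      archetypes = list(RYGB = archetypeDefaults("RYGB"),
                                        HEALTHY = archetypeDefaults("HEALTHY"),
                                        T1D = archetypeDefaults("T1D")),
                      scenario = c("matched", "confounded")) {
  scenario <- match.arg(scenario)
  new("SimConfig", nSubjects = as.integer(nSubjects),
      nDays = as.integer(nDays), interval = interval,
      seed = as.integer(seed), startDate = as.Date(startDate),
      archetypes = archetypes, scenario = scenario)
}
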