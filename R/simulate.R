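# Synthetic three-archetype CGM cohort simulator.

# Bi-exponential kernel on a minute grid, normalized to peak 1.
.biexp <- function(uMin, rise, fall) {
  k <- exp(-uMin / fall) - exp(-uMin / rise)
  uStar <- log(fall / rise) * rise * fall / (fall - rise)
  k / (exp(-uStar / fall) - exp(-uStar / rise))
}

# Stationary AR(1) series of length n with lag-1 correlation rho and
# stationary SD sigma.
.ar1 <- function(n, rho, sigma) {
  if (sigma <= 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Smooth floor near 45 mg/dL: latent glucose is defended against free fall
# (counterregulation), which also keeps latent traces strictly inside the
# reportable sensor span so they are never clipped.
.softFloor <- function(g, floor = 45, scale = 3) {
  floor + scale * log1p(exp((g - floor) / scale))
}

#' Simulate one subject's latent and sensor glucose traces
#'
#' The latent trace is a circadian basal sinusoid (24-h period, minimum near
#' 03:00) plus bi-exponential meal-excursion kernels (with, for archetypes
#' prone to reactive hypoglycaemia, a delayed negative undershoot kernel after
#' meals), plus smooth AR(1) physiological wander and, where parameterized, an
#' additional nocturnal instability component, passed through a soft
#' counterregulatory floor near 45 mg/dL. The sensor trace adds AR(1)
#' multiplicative noise scaled to the archetype's MARD target, rounds to
#' integer mg/dL, and clips to the reportable span [40, 400].
#'
#' @param params an \linkS4class{ArchetypeParams}.
#' @param days number of recording days.
#' @param seed integer seed; the same seed reproduces the traces exactly.
#' @param subjectId subject identifier for the returned traces.
#' @param startDate first calendar date.
#' @param interval grid interval, minutes.
#' @return list with \code{latent} and \code{sensor}
#'   (\linkS4class{CgmTrace}), and \code{nClipped}, the number of sensor
#'   readings clipped to the span.
#' @export
simulateSubject <- function(params, days = 10, seed = 1, subjectId = "S1",
                            startDate = as.Date("2023-03-01"), interval = 5) {
  stopifnot(is(params, "ArchetypeParams"))
  withSeed(seed, {
    slotsPerDay <- as.integer(1440 / interval)
    n <- days * slotsPerDay
    t0 <- as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC")
    time <- t0 + (0:(n - 1)) * interval * 60
    tMin <- (0:(n - 1)) * interval          # minutes since start
    hod <- (tMin / 60) %% 24

    circ <- params@circadianAmplitude * cospi((hod - 15) / 12)
    wander <- .ar1(n, params@wanderRho, params@wanderSd)
    latent <- params@basalMean + circ + wander

    if (params@nocturnalSd > 0) {
      noct <- .ar1(n, params@nocturnalRho, params@nocturnalSd)
      dNight <- pmin(abs(hod - 3), 24 - abs(hod - 3))
      wNight <- pmin(1, pmax(0, (4.5 - dNight)))   # 1 inside the night block
      latent <- latent + noct * wNight
    }

    for (d in 0:(days - 1)) {
      mt <- stats::rnorm(length(params@mealTimes), params@mealTimes,
                         params@mealTimeSd)
      if (stats::runif(1) < params@extraMealProb)
        mt <- c(mt, stats::runif(1, params@extraMealWindow[1],
                                 params@extraMealWindow[2]))
      mt <- pmin(pmax(mt, 6.25), 22.5)
      for (m in sort(mt)) {
        mealMin <- d * 1440 + m * 60
        peak <- stats::rlnorm(1, log(params@peakMedian), params@peakSdlog)
        u <- tMin - mealMin
        span <- which(u >= 0 & u <= 600)
        if (length(span))
          latent[span] <- latent[span] +
            peak * .biexp(u[span], params@riseMin, params@fallMin)
        if (stats::runif(1) < params@undershootProb) {
          depth <- pmax(0, stats::rnorm(1, params@undershootDepthMean,
                                        params@undershootDepthSd))
          u2 <- u - params@undershootDelayMin
          span2 <- which(u2 >= 0 & u2 <= 900)
          if (length(span2))
            latent[span2] <- latent[span2] -
              depth * .biexp(u2[span2], params@undershootRiseMin,
                             params@undershootFallMin)
        }
      }
    }

    latent <- .softFloor(latent)
    # Relative noise SD giving E|eps| = mardTarget/100 for AR(1)-normal eps.
    relSd <- params@mardTarget / 100 / sqrt(2 / pi)
    eps <- .ar1(n, params@noiseRho, relSd)
    sensor <- round(latent * (1 + eps))
    nClipped <- sum(sensor < 40 | sensor > 400)
    sensor <- pmin(pmax(sensor, 40), 400)

    list(latent = CgmTrace(subjectId, time, round(latent, 2),
                           interval = interval),
         sensor = CgmTrace(subjectId, time, sensor, interval = interval),
         nClipped = nClipped)
  })
}

#' Remove wear-gap bursts from a trace
#'
#' Deletes bursts of consecutive readings (geometric burst lengths with the
#' given mean) at uniformly drawn positions until exactly
#' \code{round(rate * n)} readings are removed, so the removed fraction is
#' within one slot of \code{rate}. At the default simulator rate the
#' remaining wear fraction stays well above the 0.7 eligibility threshold.
#'
#' @param trace a \linkS4class{CgmTrace}.
#' @param rate fraction of readings to remove, in [0, 0.3).
#' @param burstMean mean burst length in slots.
#' @param seed integer seed.
#' @return a \linkS4class{CgmTrace} with the readings removed.
#' @export
injectDropout <- function(trace, rate, burstMean = 6, seed = 1) {
  if (rate < 0 || rate >= 0.3) stop("dropout rate must lie in [0, 0.3)")
  n <- length(trace)
  target <- round(rate * n)
  if (target == 0) return(trace)
  withSeed(seed, {
    drop <- logical(n)
    while (sum(drop) < target) {
      len <- 1 + stats::rgeom(1, 1 / burstMean)
      start <- sample.int(n, 1)
      ix <- start:min(n, start + len - 1)
      drop[ix] <- TRUE
      if (sum(drop) > target) {
        # trim the overshoot: un-drop the last few marked slots of this burst
        excess <- sum(drop) - target
        newly <- rev(ix[drop[ix]])
        drop[newly[seq_len(excess)]] <- FALSE
      }
    }
    CgmTrace(trace@subjectId, trace@time[!drop], trace@glucose[!drop],
             interval = trace@interval)
  })
}

#' Mean absolute relative difference between sensor and latent traces
#'
#' @param sensor,latent \linkS4class{CgmTrace} on the same grid (the sensor
#'   trace may have gaps; readings are paired by timestamp).
#' @return MARD in percent.
#' @export
mard <- function(sensor, latent) {
  if (sensor@interval != latent@interval)
    stop("misaligned grids: traces have different nominal intervals")
  ix <- match(as.numeric(sensor@time), as.numeric(latent@time))
  if (anyNA(ix)) stop("misaligned grids: sensor timestamps absent from latent trace")
  if (length(ix) == 0) stop("no paired readings")
  100 * mean(abs(sensor@glucose - latent@glucose[ix]) / latent@glucose[ix])
}

# Covariates for one cohort. Matched scenario: common age distribution,
# cohort-specific BMI, sex exactly 36 F / 9 M per 45 (proportion preserved at
# other sizes). Confounded pools additionally shift age and BMI.
.simulateCovariatesOne <- function(name, n, seed, ageShift = 0, bmiShift = 0,
                                   exactSex = TRUE, prefix = name) {
  bmiPar <- switch(name, RYGB = c(26.7, 5.2), HEALTHY = c(25.5, 2.8),
                   T1D = c(27.4, 6.1))
  withSeed(seed, {
    rtnorm <- function(n, mean, sd, lo, hi) {
      x <- stats::rnorm(n, mean, sd)
      while (any(bad <- x < lo | x > hi))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
      x
    }
    age <- rtnorm(n, 48 + ageShift, 14, 18, 80)
    bmi <- rtnorm(n, bmiPar[1] + bmiShift, bmiPar[2], 16, 55)
    sex <- if (exactSex) {
      nF <- round(n * 36 / 45)
      sample(rep(c(1, 0), c(nF, n - nF)))
    } else stats::rbinom(n, 1, 0.8)
    data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
               age = round(age, 1), sex = sex, bmi = round(bmi, 1),
               cohort = name, stringsAsFactors = FALSE)
  })
}

#' Simulate covariate tables only
#'
#' Fast path used for matching studies: the matched scenario draws identical
#' covariate distributions per cohort with sex exactly 36 F / 9 M; the
#' confounded scenario draws the RYGB reference plus comparison pools
#' \code{poolFactor} times larger with age shifted by \code{ageShift} years
#' and BMI by \code{bmiShift} kg/m2.
#'
#' @param nSubjects reference cohort size.
#' @param seed integer master seed.
#' @param scenario \code{"matched"} or \code{"confounded"}.
#' @param poolFactor pool size multiplier (confounded scenario).
#' @param ageShift,bmiShift pool covariate shifts (confounded scenario).
#' @return named list of covariate data.frames (\code{RYGB}, \code{HEALTHY},
#'   \code{T1D}).
#' @export
simulateCovariates <- function(nSubjects = 45, seed = 20260301,
                               scenario = c("matched", "confounded"),
                               poolFactor = 4, ageShift = 8, bmiShift = -2) {
  scenario <- match.arg(scenario)
  out <- list()
  for (name in c("RYGB", "HEALTHY", "T1D")) {
    sd <- childSeed(seed, paste0("cov-", name))
    out[[name]] <- if (scenario == "matched" || name == "RYGB")
      .simulateCovariatesOne(name, nSubjects, sd)
    else
      .simulateCovariatesOne(name, nSubjects * poolFactor, sd,
                             ageShift = ageShift, bmiShift = bmiShift,
                             exactSex = FALSE)
  }
  out
}

#' Simulate the three-cohort CGM dataset
#'
#' Draws covariates and traces for the RYGB, healthy-control, and
#' type-1-diabetes archetype cohorts, injects wear gaps, and retains the
#' noise-free latent traces. Output is fully determined by the configuration
#' seed: each subject's trace seed is derived by stable hashing of the
#' subject id, so adding a subject never perturbs the others.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{CgmSimulation}.
#' @examples
#' \donttest{
#' sim <- simulateCohorts(simConfig(nSubjects = 4, nDays = 3, seed = 7))
#' sim
#' }
#' @export
simulateCohorts <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  covs <- simulateCovariates(config@nSubjects, config@seed, config@scenario)
  cohortsOut <- list()
  latentAll <- list()
  for (name in names(covs)) {
    cov <- covs[[name]]
    params <- config@archetypes[[name]]
    trs <- list()
    for (id in cov$subject_id) {
      sub <- simulateSubject(params, days = config@nDays,
                             seed = childSeed(config@seed, id),
                             subjectId = id, startDate = config@startDate,
                             interval = config@interval)
      sensor <- injectDropout(sub$sensor, params@dropoutRate,
                              params@dropoutBurstMean,
                              seed = childSeed(config@seed,
                                               paste0(id, "-dropout")))
      trs[[id]] <- sensor
      latentAll[[id]] <- sub$latent
    }
    cohortsOut[[name]] <- CgmCohort(name, trs, cov)
  }
  new("CgmSimulation", cohorts = cohortsOut, latent = latentAll,
      config = config)
}
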