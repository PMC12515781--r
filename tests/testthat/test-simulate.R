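test_that("degenerate parameters collapse to a constant basal trace", {
  p <- archetypeDefaults("HEALTHY")
  p@mealTimes <- numeric(); p@extraMealProb <- 0
  p@circadianAmplitude <- 0; p@wanderSd <- 0; p@nocturnalSd <- 0
  p@mardTarget <- 0; p@undershootProb <- 0
  sub <- simulateSubject(p, days = 1, seed = 4)
  expect_equal(unique(glucoseValues(sub$sensor)), round(p@basalMean))
  expect_equal(length(sub$sensor), 288)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulateSubject(archetypeDefaults("RYGB"), days = 2, seed = 99)
  b <- simulateSubject(archetypeDefaults("RYGB"), days = 2, seed = 99)
  expect_identical(glucoseValues(a$sensor), glucoseValues(b$sensor))
  expect_identical(glucoseValues(a$latent), glucoseValues(b$latent))
  c2 <- simulateSubject(archetypeDefaults("RYGB"), days = 2, seed = 100)
  expect_false(identical(glucoseValues(a$sensor), glucoseValues(c2$sensor)))

  s1 <- simulateCohorts(simConfig(nSubjects = 2, nDays = 2, seed = 5))
  s2 <- simulateCohorts(simConfig(nSubjects = 2, nDays = 2, seed = 5))
  expect_identical(lapply(cohorts(s1), covariates),
                   lapply(cohorts(s2), covariates))
  expect_identical(glucoseValues(traces(cohorts(s1)$T1D)[[1]]),
                   glucoseValues(traces(cohorts(s2)$T1D)[[1]]))
})

test_that("post-bariatric meals rise fast and undershoot their baseline", {
  p <- archetypeDefaults("RYGB")
  p@mealTimes <- 12; p@extraMealProb <- 0
  crossHigh <- 0; undershoot <- 0; dipLow <- 0
  for (s in 1:100) {
    sub <- simulateSubject(p, days = 1, seed = s)
    g <- glucoseValues(sub$latent)
    h <- (as.numeric(readingTimes(sub$latent)) %% 86400) / 3600
    base <- mean(g[h >= 10 & h < 11.5])
    gw <- g[h >= 12 & h <= 16]
    if (max(gw) > 140) crossHigh <- crossHigh + 1
    if (min(gw) < base - 8) undershoot <- undershoot + 1
    if (min(gw) < 70) dipLow <- dipLow + 1
  }
  expect_gte(crossHigh / 100, 0.8)   # tall fast excursions
  expect_gte(undershoot / 100, 0.5)  # reactive dip below pre-meal baseline
  # dips below 70 occur at the rate the cohort event frequency implies
  expect_gte(dipLow / 100, 0.05)
  expect_lte(dipLow / 100, 0.5)
})

test_that("latent traces stay inside the sensor span at defaults", {
  for (name in c("RYGB", "T1D", "HEALTHY")) {
    for (s in 1:5) {
      sub <- simulateSubject(archetypeDefaults(name), days = 10, seed = s)
      expect_gt(min(glucoseValues(sub$latent)), 40)
      expect_lt(max(glucoseValues(sub$latent)), 400)
    }
  }
})

test_that("dropout removes the requested fraction in bursts", {
  tr <- constantTrace(100, nDays = 10)
  expect_identical(injectDropout(tr, 0, seed = 1), tr)
  out <- injectDropout(tr, 0.1, burstMean = 6, seed = 2)
  expect_equal(length(out), 2880 - 288)
  expect_error(injectDropout(tr, 0.3, seed = 1), "rate")
  # default simulator rate keeps subjects eligible
  p <- archetypeDefaults("RYGB")
  out <- injectDropout(tr, p@dropoutRate, p@dropoutBurstMean, seed = 3)
  expect_gte(wearFraction(out, as.Date("2023-03-01"), 10), 0.7)
  # deterministic
  expect_identical(readingTimes(injectDropout(tr, 0.1, seed = 9)),
                   readingTimes(injectDropout(tr, 0.1, seed = 9)))
})

test_that("MARD computes the mean absolute relative difference", {
  tr <- constantTrace(100, nDays = 1)
  expect_equal(mard(tr, tr), 0)
  infl <- CgmTrace("S1", readingTimes(tr), glucoseValues(tr) * 1.1)
  expect_equal(mard(infl, tr), 10)
  short <- CgmTrace("S1", readingTimes(tr)[1:100], glucoseValues(tr)[1:100])
  expect_equal(mard(short, tr), 0)    # pairing by timestamp
  other <- CgmTrace("S1", readingTimes(tr) + 60, glucoseValues(tr))
  expect_error(mard(other, tr), "misaligned")
})

test_that("cohort structure follows the study design", {
  sim <- simulateCohorts(simConfig(nSubjects = 45, nDays = 1, seed = 88))
  for (co in cohorts(sim)) {
    expect_length(traces(co), 45)
    expect_equal(sum(covariates(co)$sex == 1), 36)
    expect_equal(sum(covariates(co)$sex == 0), 9)
  }
  covs <- simulateCovariates(45, seed = 88, scenario = "confounded")
  expect_equal(nrow(covs$RYGB), 45)
  expect_equal(nrow(covs$HEALTHY), 180)
  expect_gt(mean(covs$HEALTHY$age), mean(covs$RYGB$age) + 4)
  expect_lt(mean(covs$HEALTHY$bmi), mean(covs$RYGB$bmi))
})
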