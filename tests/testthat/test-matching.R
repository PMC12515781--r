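test_that("SMD matches the closed-form definitions", {
  x <- c(3, 4, 5, 6, 7)
  expect_equal(smd(x, x), 0)
  # unit-SD groups with means one apart have SMD exactly 1
  u <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  expect_equal(smd(u + 1, u), 1, tolerance = 1e-12)
  # direct formula check on arbitrary samples
  b <- c(10, 12, 9, 14)
  c2 <- c(8, 7, 11)
  expect_equal(smd(b, c2),
               (mean(b) - mean(c2)) / sqrt((var(b) + var(c2)) / 2))
  # binary: identical 36/45 female composition gives exactly 0
  sexA <- rep(c(1, 0), c(36, 9))
  expect_equal(smd(sexA, sexA, kind = "binary"), 0)
  expect_equal(smd(c(1, 1, 0, 0), c(1, 0, 0, 0), kind = "binary"),
               0.25 / sqrt((0.25 + 0.1875) / 2))
  # degenerate: no variance but different means
  expect_error(smd(c(1, 1), c(2, 2)), "degenerate")
  expect_equal(smd(c(1, 1), c(1, 1), kind = "binary"), 0)
})

test_that("propensity model recovers the null and the one-covariate logit", {
  ref <- data.frame(subject_id = sprintf("R%02d", 1:40),
                    age = rep(c(40, 50, 60, 70), 10),
                    sex = rep(c(0, 1), 20), bmi = rep(c(22, 30), each = 20))
  pool <- ref; pool$subject_id <- sprintf("P%02d", 1:40)
  m <- fitPropensity(ref, pool)
  expect_true(m@converged)
  expect_true(all(abs(m@coefficients[-1]) < 1e-6))
  expect_equal(unname(propensityScores(m)), rep(0.5, 80), tolerance = 1e-6)

  # single binary covariate, 2x2 counts (20,10 / 10,20): coef = log OR
  ref2 <- data.frame(subject_id = sprintf("R%02d", 1:30),
                     x = rep(c(1, 0), c(20, 10)))
  pool2 <- data.frame(subject_id = sprintf("P%02d", 1:30),
                      x = rep(c(1, 0), c(10, 20)))
  m2 <- fitPropensity(ref2, pool2, covariateCols = "x")
  expect_equal(unname(m2@coefficients["x"]), log(4), tolerance = 1e-6)
  expect_true(all(propensityScores(m2) > 0 & propensityScores(m2) < 1))
})

test_that("perfect separation is reported with the covariate name", {
  ref <- data.frame(subject_id = sprintf("R%02d", 1:10), age = 60 + 1:10)
  pool <- data.frame(subject_id = sprintf("P%02d", 1:10), age = 20 + 1:10)
  expect_error(fitPropensity(ref, pool, covariateCols = "age"),
               "separation.*age")
})

test_that("greedy matching follows the documented rules", {
  # identity matching when the pool copies the reference
  ref <- c(A = 0.3, B = 0.5, C = 0.8)
  pool <- c(a = 0.3, b = 0.5, c = 0.8)
  mr <- matchNearest(ref, pool, caliper = NULL)
  p <- matchedPairs(mr)
  expect_equal(p$distance, rep(0, 3))
  expect_equal(p$matched_id[match(c("A", "B", "C"), p$reference_id)],
               c("a", "b", "c"))

  # worked example: greedy equals the enumerated optimum here
  ref <- c(R1 = 0.9, R2 = 0.1)
  pool <- c(P1 = 0.8, P2 = 0.2, P3 = 0.5)
  p <- matchedPairs(matchNearest(ref, pool, caliper = NULL))
  expect_equal(p$matched_id[match(c("R1", "R2"), p$reference_id)],
               c("P1", "P2"))
  tot <- sum(p$distance)
  expect_equal(tot, enumerateBestAssignment(ref, pool), tolerance = 1e-9)

  # tight caliper on disjoint score ranges leaves everything unmatched
  mr <- matchNearest(c(A = 0.9, B = 0.95), c(a = 0.05, b = 0.1),
                     caliper = 0.01)
  expect_equal(nrow(matchedPairs(mr)), 0)
  expect_setequal(unmatchedReference(mr), c("A", "B"))
  expect_error(matchNearest(c(A = 0.5), numeric()), "empty pool")
})

test_that("greedy matcher agrees with an independent implementation", {
  set.seed(55)
  for (i in 1:50) {
    nr <- sample(2:5, 1); np <- sample(nr:6, 1)
    ref <- setNames(runif(nr, 0.05, 0.95), paste0("R", seq_len(nr)))
    pool <- setNames(runif(np, 0.05, 0.95), paste0("P", seq_len(np)))
    got <- matchedPairs(matchNearest(ref, pool, caliper = NULL))
    want <- oracleGreedy(ref, pool)
    expect_equal(got[, c("reference_id", "matched_id")], want)
    expect_false(anyDuplicated(got$matched_id) > 0)
  }
})

test_that("balance report flags the 0.1 threshold correctly", {
  set.seed(8)
  ref <- data.frame(subject_id = sprintf("R%02d", 1:20),
                    age = rnorm(20, 50, 10), sex = rep(c(0, 1), 10),
                    bmi = rnorm(20, 27, 4))
  br <- balanceReport(ref, ref, ref)
  expect_equal(maxAbsSmdAfter(br), 0)
  expect_true(isBalanced(br))
  shifted <- ref
  shifted$age <- shifted$age + 8
  br2 <- balanceReport(ref, shifted, shifted)
  expect_false(isBalanced(br2))
  expect_gt(abs(balanceTable(br2)$smd_post[1]), 0.1)
})

test_that("matching a confounded pool restores covariate balance", {
  covs <- simulateCovariates(45, seed = 314, scenario = "confounded")
  # pools are genuinely shifted before matching
  expect_gt(abs(smd(covs$RYGB$age, covs$HEALTHY$age)), 0.15)
  expect_gt(abs(smd(covs$RYGB$bmi, covs$HEALTHY$bmi)), 0.3)
  pm <- propensityMatch(covs$RYGB, covs$HEALTHY)
  expect_equal(nrow(matchedPairs(pm$match)) +
                 length(unmatchedReference(pm$match)), 45)
  expect_lt(maxAbsSmdAfter(pm$balance), 0.1)
  # exact sex matching keeps the sex SMD at zero
  tab <- balanceTable(pm$balance)
  expect_equal(tab$smd_post[tab$covariate == "sex"], 0)
  # 1:1 without replacement
  expect_false(anyDuplicated(matchedPairs(pm$match)$matched_id) > 0)
})
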