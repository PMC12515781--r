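test_that("CSV ingestion parses, clips, deduplicates and reports", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,timestamp,glucose_mgdl",
               "S1,2023-03-01T00:00:00,100",
               "S1,2023-03-01T00:05:00,105",
               "S1,2023-03-01T00:10:00,110"), f)
  co <- readCgmCsv(f)
  expect_length(traces(co), 1)
  expect_equal(glucoseValues(traces(co)$S1), c(100, 105, 110))
  expect_equal(co@metadata$parseReport$rows_read, 3)
  expect_equal(co@metadata$parseReport$duplicates, 0)

  # out-of-span value is clipped, duplicate slot dropped (first wins)
  writeLines(c("subject_id,timestamp,glucose_mgdl",
               "S1,2023-03-01T00:00:00,420",
               "S1,2023-03-01T00:05:00,90",
               "S1,2023-03-01T00:05:00,95"), f)
  co <- readCgmCsv(f)
  expect_equal(glucoseValues(traces(co)$S1), c(400, 90))
  expect_equal(co@metadata$parseReport$rows_clipped, 1)
  expect_equal(co@metadata$parseReport$duplicates, 1)
})

test_that("ingestion errors: missing column fails fast, bad rows collected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,when,glucose_mgdl", "S1,2023-03-01T00:00:00,100"), f)
  expect_error(readCgmCsv(f), "missing column: timestamp")
  writeLines(c("subject_id,timestamp,glucose_mgdl",
               "S1,not-a-time,100", "S1,also-bad,100",
               "S1,2023-03-01T00:00:00,100"), f)
  expect_error(readCgmCsv(f), "failed to parse")
  writeLines(c("subject_id,timestamp,glucose_mgdl",
               "S1,not-a-time,100",
               "S1,2023-03-01T00:00:00,100",
               "S1,2023-03-01T00:05:00,101"), f)
  co <- readCgmCsv(f)
  expect_equal(co@metadata$parseReport$rows_dropped, 1)
  expect_length(traces(co)$S1, 2)
})

test_that("timestamps are snapped to the nearest grid slot", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,timestamp,glucose_mgdl",
               "S1,2023-03-01T00:00:40,100",
               "S1,2023-03-01T00:04:10,105"), f)
  co <- readCgmCsv(f)
  expect_equal(format(readingTimes(traces(co)$S1), "%H:%M"),
               c("00:00", "00:05"))
})

test_that("write/read round trip reproduces simulated traces exactly", {
  sim <- simulateCohorts(simConfig(nSubjects = 3, nDays = 2, seed = 11))
  co <- cohorts(sim)$RYGB
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeCgmCsv(co, f1, f2)
  back <- readCgmCsv(f1, f2, name = "RYGB")
  for (id in names(traces(co))) {
    expect_identical(as.numeric(readingTimes(traces(back)[[id]])),
                     as.numeric(readingTimes(traces(co)[[id]])))
    expect_equal(glucoseValues(traces(back)[[id]]),
                 glucoseValues(traces(co)[[id]]))
  }
  expect_equal(covariates(back)$bmi, covariates(co)$bmi)
})

test_that("wear fraction counts observed readings against the grid", {
  full <- constantTrace(100, nDays = 10)
  expect_equal(wearFraction(full, as.Date("2023-03-01"), 10), 1.0)

  # exactly 70% of slots present is eligible (inclusive threshold)
  keep <- which(seq(0, 2879) %% 10 < 7)   # 2016 slots spread over all 10 days
  partial <- CgmTrace("S1", readingTimes(full)[keep],
                      glucoseValues(full)[keep])
  expect_equal(wearFraction(partial, as.Date("2023-03-01"), 10), 0.70)
  win <- selectWindow(partial, 10, 0.70)
  expect_equal(wearFractionOf(win), 0.70)

  # window disjoint from the trace span
  expect_equal(wearFraction(full, as.Date("2024-01-01"), 10), 0)
})

test_that("earliest qualifying window is selected", {
  tr12 <- constantTrace(100, nDays = 12)
  win <- selectWindow(tr12)
  expect_equal(windowStart(win), as.Date("2023-03-01"))
  expect_equal(wearFractionOf(win), 1.0)

  # day 2 fully missing: earliest window keeps 9/10 days = 0.9 wear
  keep <- !(as.Date(readingTimes(tr12), tz = "UTC") == as.Date("2023-03-02"))
  holed <- CgmTrace("S1", readingTimes(tr12)[keep], glucoseValues(tr12)[keep])
  win <- selectWindow(holed)
  expect_equal(windowStart(win), as.Date("2023-03-01"))
  expect_equal(wearFractionOf(win), 0.9)
})

test_that("short or sparse traces raise an ineligibility error with best wear", {
  tr5 <- constantTrace(100, nDays = 5)
  err <- tryCatch(selectWindow(tr5), cgmIneligibleError = function(e) e)
  expect_s3_class(err, "cgmIneligibleError")
  expect_equal(err$bestWear, 0.5)

  # long enough span but too sparse everywhere
  tr <- constantTrace(100, nDays = 12)
  thin <- CgmTrace("S1", readingTimes(tr)[seq(1, 3456, by = 2)],
                   glucoseValues(tr)[seq(1, 3456, by = 2)])
  err <- tryCatch(selectWindow(thin), cgmIneligibleError = function(e) e)
  expect_s3_class(err, "cgmIneligibleError")
  expect_lt(err$bestWear, 0.7)
})

test_that("day/night split uses half-open clock intervals and partitions", {
  tm <- as.POSIXct(c("2023-03-01 05:55:00", "2023-03-01 06:00:00",
                     "2023-03-01 23:55:00", "2023-03-02 00:00:00"),
                   tz = "UTC")
  tr <- CgmTrace("S1", tm, rep(100, 4))
  sp <- splitPeriods(tr)
  expect_equal(format(readingTimes(sp$day), "%H:%M"), c("06:00", "23:55"))
  expect_equal(format(readingTimes(sp$night), "%H:%M"), c("05:55", "00:00"))

  oneDay <- constantTrace(100, nDays = 1)
  sp <- splitPeriods(oneDay)
  expect_length(sp$day, 216)    # 18 h x 12 slots/h
  expect_length(sp$night, 72)   # 6 h x 12 slots/h
})

test_that("partition and wear monotonicity hold on random gappy traces", {
  set.seed(42)
  for (i in 1:25) {
    tr <- randomTrace(500 + i)
    sp <- splitPeriods(tr)
    expect_equal(length(sp$day) + length(sp$night), length(sp$overall))
    # adding readings can only increase wear
    w1 <- wearFraction(tr, as.Date("2023-03-01"), 2)
    expect_gte(1, w1)
    half <- CgmTrace("S1", readingTimes(tr)[c(TRUE, FALSE)],
                     glucoseValues(tr)[c(TRUE, FALSE)])
    expect_lte(wearFraction(half, as.Date("2023-03-01"), 2), w1)
  }
})
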