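test_that("band times follow the closed-below/open-above boundary rules", {
  expect_equal(unname(bandTimes(rep(100, 10))[c("tir", "titr", "tar", "tbr")]),
               c(100, 100, 0, 0))
  bt <- bandTimes(c(rep(200, 5), rep(100, 5)))
  expect_equal(unname(bt[c("tar", "tir")]), c(50, 50))

  # boundary readings: 54 is level-1 not level-2; 70 is in range, not below
  bt <- bandTimes(c(54, 70))
  expect_equal(unname(bt[c("time_l1", "time_l2", "tbr", "tir")]),
               c(50, 0, 50, 50))
  expect_error(bandTimes(numeric()), class = "cgmNoDataError")
})

test_that("CV is the sample SD over the mean in percent", {
  expect_equal(cvPercent(rep(90, 5)), 0)
  expect_equal(cvPercent(c(80, 120)), 100 * sd(c(80, 120)) / 100,
               tolerance = 1e-12)
  expect_equal(cvPercent(c(80, 120)), 28.2842712, tolerance = 1e-6)
  x <- c(88, 132, 101, 95)
  expect_equal(cvPercent(3.7 * x), cvPercent(x))
  expect_error(cvPercent(100), class = "cgmNoDataError")
})

test_that("GMI is the published linear map of mean glucose", {
  expect_equal(gmi(139.1), 3.31 + 0.02392 * 139.1)
  expect_equal(round(gmi(139.1), 2), 6.64)
  expect_equal(gmi(100), 5.702)
  expect_true(all(diff(gmi(seq(50, 300, by = 10))) > 0))
  expect_error(gmi(0))
})

test_that("event detection implements the 3-point start and recovery rules", {
  expect_equal(nrow(detectEvents(makeTrace(c(65, 65, 60)), "hypo_l1")), 1)
  expect_equal(detectEvents(makeTrace(c(65, 65, 60)), "hypo_l1")$duration_min,
               15)
  expect_equal(nrow(detectEvents(makeTrace(c(65, 75, 65, 65)), "hypo_l1")), 0)

  # a single recovered reading does not terminate the event
  ev <- detectEvents(makeTrace(c(60, 60, 60, 72, 60, 60, 60)), "hypo_l1")
  expect_equal(ev$n_readings, 7)
  expect_equal(ev$duration_min, 35)
  expect_equal(ev$extremum, 60)

  # three recovered readings do: two separate events
  g <- c(60, 60, 60, 75, 75, 75, 60, 60, 60)
  ev <- detectEvents(makeTrace(g), "hypo_l1")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration_min, c(15, 15))

  # hyperglycaemia is symmetric, above 180
  ev <- detectEvents(makeTrace(c(190, 200, 185, 100, 100, 100)), "hyper")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$extremum, 200)
})

test_that("gaps reset the consecutive-reading count and end events", {
  # 3 sub-threshold readings split 2|1 by a missing slot: no event
  tr <- makeTrace(c(65, 65, 65), gapsAfter = 2)
  expect_equal(nrow(detectEvents(tr, "hypo_l1")), 0)
  # an in-band gap inside a long run splits it into two events
  tr <- makeTrace(c(65, 65, 65, 65, 65, 65), gapsAfter = 3)
  ev <- detectEvents(tr, "hypo_l1")
  expect_equal(nrow(ev), 2)
  # inserting a gap in-band never creates an event
  tr <- makeTrace(c(100, 100, 100, 100), gapsAfter = 2)
  expect_equal(nrow(detectEvents(tr, "hypo_l1")), 0)
})

test_that("event detector agrees with the state-machine oracle on random series", {
  set.seed(202)
  cfg <- metricConfig()
  for (i in 1:400) {
    n <- sample(10:40, 1)
    g <- round(runif(n, 45, 110))
    tr <- makeTrace(g, gapsAfter = sample(1:(n - 1), sample(0:2, 1)))
    ev <- detectEvents(tr, "hypo_l1", cfg)
    or <- oracleEvents(tr, 70, "below")
    expect_equal(nrow(ev), nrow(or))
    if (nrow(ev)) {
      expect_equal(as.numeric(ev$start),
                   as.numeric(readingTimes(tr))[or$startIdx])
      expect_equal(ev$n_readings, or$endIdx - or$startIdx + 1)
    }
  }
})

test_that("level-2 event spans are nested inside level-1 spans", {
  set.seed(77)
  for (i in 1:200) {
    g <- round(runif(30, 42, 90))
    tr <- makeTrace(g)
    e2 <- detectEvents(tr, "hypo_l2")
    e1 <- detectEvents(tr, "hypo_l1")
    expect_lte(sum(bandTimes(g)[["time_l2"]]), sum(bandTimes(g)[["tbr"]]))
    if (nrow(e2)) {
      for (k in seq_len(nrow(e2))) {
        inside <- any(e1$start <= e2$start[k] & e1$end >= e2$end[k])
        expect_true(inside)
      }
    }
  }
})

test_that("event summaries report count and mean duration", {
  expect_equal(eventSummary(data.frame(duration_min = numeric()))$count, 0)
  expect_true(is.na(eventSummary(data.frame(duration_min = numeric()))$meanDuration))
  expect_equal(eventSummary(data.frame(duration_min = c(15, 25))),
               list(count = 2, meanDuration = 20))
  expect_equal(eventSummary(data.frame(duration_min = 15))$meanDuration, 15)
})

test_that("metric panel populates all periods and assigns events by start", {
  tr <- constantTrace(100, nDays = 10)
  p <- metricPanel(tr)
  expect_equal(p$period, c("overall", "day", "night"))
  expect_equal(p$mean_glucose, rep(100, 3))
  expect_equal(p$cv, rep(0, 3))
  expect_equal(p$tir, rep(100, 3))
  expect_equal(sum(p$n_l1_events), 0)

  # one nocturnal 3-point dip to 50: L2 and L1 event at night, none by day
  g <- rep(100, 288)
  g[25:27] <- 50       # 02:00-02:10
  p <- metricPanel(makeTrace(g))
  expect_equal(p$n_l2_events[p$period == "night"], 1)
  expect_equal(p$n_l1_events[p$period == "night"], 1)
  expect_equal(p$n_l2_events[p$period == "day"], 0)

  # overall TBR is the reading-count-weighted mix of day and night TBR
  set.seed(9)
  tr <- randomTrace(600)
  p <- metricPanel(tr)
  w <- p$n_readings[2:3]
  expect_equal(p$tbr[1], sum(p$tbr[2:3] * w) / sum(w), tolerance = 1e-9)
})

test_that("panel conservation identities hold on random traces", {
  set.seed(31)
  for (i in 1:50) {
    p <- metricPanel(randomTrace(400))
    expect_equal(p$tir + p$tar + p$tbr, rep(100, 3), tolerance = 1e-9)
    expect_equal(p$tbr, p$time_l1 + p$time_l2, tolerance = 1e-9)
    expect_true(all(p$titr <= p$tir + 1e-9))
  }
})
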