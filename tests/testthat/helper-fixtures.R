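# Fixtures and independent oracles used across the suite.

T0 <- as.POSIXct("2023-03-01 00:00:00", tz = "UTC")

# A trace from glucose values on the 5-min grid; `gapsAfter` marks reading
# indices after which one extra empty slot is inserted.
makeTrace <- function(values, start = T0, interval = 5, gapsAfter = integer(),
                      id = "S1") {
  offsets <- seq_along(values) - 1
  for (g in sort(gapsAfter)) {
    late <- seq_along(values) > g
    offsets[late] <- offsets[late] + 1
  }
  CgmTrace(id, start + offsets * interval * 60, values, interval = interval)
}

# A complete nDays trace of constant glucose.
constantTrace <- function(value = 100, nDays = 10, id = "S1", start = T0) {
  makeTrace(rep(value, nDays * 288), start = start, id = id)
}

randomTrace <- function(n, id = "S1", pGap = 0.1) {
  g <- round(runif(n, 41, 399))
  keep <- runif(n) > pGap
  keep[1] <- TRUE
  tm <- (T0 + (0:(n - 1)) * 300)[keep]
  CgmTrace(id, tm, g[keep])
}

# Independent event-detection oracle: explicit reading-by-reading state
# machine over gap-free segments (structure deliberately different from the
# package's run-length implementation).
oracleEvents <- function(trace, threshold, direction = c("below", "above"),
                         minEvent = 3, minRecovery = 3) {
  direction <- match.arg(direction)
  g <- glucoseValues(trace)
  tm <- as.numeric(readingTimes(trace))
  step <- nominalInterval(trace) * 60
  segBreaks <- c(0, which(diff(tm) > step + 0.5), length(g))
  out <- list()
  for (s in seq_len(length(segBreaks) - 1)) {
    ix <- (segBreaks[s] + 1):segBreaks[s + 1]
    gg <- g[ix]
    beyond <- if (direction == "below") gg < threshold else gg > threshold
    n <- length(gg)
    i <- 1
    while (i <= n) {
      if (i + minEvent - 1 <= n && all(beyond[i:(i + minEvent - 1)])) {
        last <- i + minEvent - 1
        j <- last + 1
        rec <- 0
        while (j <= n) {
          if (beyond[j]) {
            last <- j; rec <- 0
          } else {
            rec <- rec + 1
            if (rec >= minRecovery) break
          }
          j <- j + 1
        }
        out[[length(out) + 1]] <- data.frame(startIdx = ix[i],
                                             endIdx = ix[last],
                                             n = last - i + 1)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(startIdx = integer(), endIdx = integer(), n = integer()))
  do.call(rbind, out)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of rank
# assignments (no ties assumed).
mwEnumerate <- function(a, b) {
  na <- length(a)
  u <- sum(outer(a, b, ">"))
  pooled <- c(a, b)
  uAll <- utils::combn(length(pooled), na, function(ix)
    sum(outer(pooled[ix], pooled[-ix], ">")))
  pl <- mean(uAll <= u); pg <- mean(uAll >= u)
  min(1, 2 * min(pl, pg))
}

# Independent greedy-matching oracle: nested loops, same rule set
# (descending reference score, nearest pool logit, lexical tie-breaks).
oracleGreedy <- function(refScores, poolScores, caliper = Inf) {
  lg <- function(p) log(p / (1 - p))
  refIds <- names(refScores)[order(-refScores, names(refScores))]
  used <- character()
  pairs <- list()
  for (rid in refIds) {
    bestId <- NA; bestD <- Inf
    for (pid in sort(names(poolScores))) {
      if (pid %in% used) next
      d <- abs(lg(poolScores[[pid]]) - lg(refScores[[rid]]))
      if (d < bestD - 1e-12) { bestD <- d; bestId <- pid }
    }
    if (!is.na(bestId) && bestD <= caliper) {
      used <- c(used, bestId)
      pairs[[length(pairs) + 1]] <- data.frame(reference_id = rid,
                                               matched_id = bestId)
    }
  }
  if (length(pairs) == 0)
    return(data.frame(reference_id = character(), matched_id = character()))
  do.call(rbind, pairs)
}

# Best (minimum total logit distance) 1:1 assignment by full enumeration.
enumerateBestAssignment <- function(refScores, poolScores) {
  lg <- function(p) log(p / (1 - p))
  poolIds <- names(poolScores)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (sel in utils::combn(length(poolIds), length(refScores),
                           simplify = FALSE)) {
    for (p in perms(poolIds[sel])) {
      tot <- sum(abs(lg(poolScores[p]) - lg(refScores)))
      best <- min(best, tot)
    }
  }
  best
}

# One 45-subject simulated archetype cohort with windowed metric panels,
# memoized so acceptance-style checks reuse a single simulation.
.simCache <- new.env(parent = emptyenv())
acceptanceSim <- function(seed = 20260301) {
  key <- as.character(seed)
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateCohorts(simConfig(seed = seed))
  .simCache[[key]]
}
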