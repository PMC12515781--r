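# Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("subjectId", "CgmTrace", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("readingTimes", "CgmTrace", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("glucoseValues", "CgmTrace", function(x) x@glucose)

#' @rdname accessors
#' @export
setMethod("nominalInterval", "CgmTrace", function(x) x@interval)

#' @export
setMethod("length", "CgmTrace", function(x) length(x@glucose))

setMethod("show", "CgmTrace", function(object) {
  n <- length(object)
  cat(sprintf("CgmTrace '%s': %d readings at %g-min nominal interval\n",
              object@subjectId, n, object@interval))
  if (n > 0) {
    cat(sprintf("  span: %s .. %s (UTC clock)\n",
                format(object@time[1], "%Y-%m-%d %H:%M"),
                format(object@time[n], "%Y-%m-%d %H:%M")))
    cat(sprintf("  glucose: %.0f .. %.0f mg/dL (mean %.1f)\n",
                min(object@glucose), max(object@glucose),
                mean(object@glucose)))
  }
})

#' @rdname accessors
#' @export
setMethod("traces", "CgmCohort", function(x) x@traces)

#' @rdname accessors
#' @export
setMethod("covariates", "CgmCohort", function(x) x@covariates)

#' @rdname accessors
#' @export
setMethod("cohortName", "CgmCohort", function(x) x@name)

#' @export
setMethod("length", "CgmCohort", function(x) length(x@traces))

setMethod("show", "CgmCohort", function(object) {
  cat(sprintf("CgmCohort '%s': %d subjects\n", object@name,
              length(object@traces)))
  if (nrow(object@covariates) && all(c("age", "bmi") %in% names(object@covariates)))
    cat(sprintf("  age %.1f +/- %.1f y, BMI %.1f +/- %.1f kg/m2\n",
                mean(object@covariates$age), stats::sd(object@covariates$age),
                mean(object@covariates$bmi), stats::sd(object@covariates$bmi)))
})

#' @rdname accessors
#' @export
setMethod("windowStart", "AnalysisWindow", function(x) x@start)

#' @rdname accessors
#' @export
setMethod("windowDays", "AnalysisWindow", function(x) x@nDays)

#' @rdname accessors
#' @export
setMethod("wearFractionOf", "AnalysisWindow", function(x) x@wearFraction)

setMethod("show", "AnalysisWindow", function(object) {
  cat(sprintf("AnalysisWindow: %d days from %s, wear fraction %.3f\n",
              object@nDays, format(object@start), object@wearFraction))
})

#' @rdname accessors
#' @export
setMethod("matchedPairs", "MatchResult", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("unmatchedReference", "MatchResult", function(x) x@unmatchedReference)

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d pairs, %d reference subjects unmatched",
              nrow(object@pairs), length(object@unmatchedReference)))
  if (!is.na(object@caliperUsed))
    cat(sprintf(", caliper %.4f (logit scale)", object@caliperUsed))
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("balanceTable", "BalanceReport", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("maxAbsSmdAfter", "BalanceReport", function(x) x@maxAbsSmdAfter)

#' @rdname accessors
#' @export
setMethod("isBalanced", "BalanceReport", function(x) x@balanced)

setMethod("show", "BalanceReport", function(object) {
  cat("BalanceReport (standardized mean differences)\n")
  tab <- object@table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-8s %-10s pre %+6.3f  post %+6.3f\n", tab$covariate[i],
                tab$kind[i], tab$smd_pre[i], tab$smd_post[i]))
  cat(sprintf("  max |SMD| after matching: %.3f (threshold %.2f) -> %s\n",
              object@maxAbsSmdAfter, object@threshold,
              if (object@balanced) "balanced" else "NOT balanced"))
})

#' @rdname accessors
#' @export
setMethod("propensityScores", "PropensityModel", function(x) x@scores)

setMethod("show", "PropensityModel", function(object) {
  cat(sprintf("PropensityModel (logit link), %s in %d iterations\n",
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
  print(round(object@coefficients, 4))
})

#' @rdname accessors
#' @export
setMethod("cohorts", "CgmSimulation", function(x) x@cohorts)

#' @rdname accessors
#' @export
setMethod("latentTraces", "CgmSimulation", function(x) x@latent)

setMethod("show", "CgmSimulation", function(object) {
  cat(sprintf("CgmSimulation ('%s' scenario, seed %d)\n",
              object@config@scenario, object@config@seed))
  for (co in object@cohorts)
    cat(sprintf("  %-8s %3d subjects, %d days\n", co@name, length(co@traces),
                object@config@nDays))
})

#' @rdname accessors
#' @export
setMethod("reportSummary", "CohortReport", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("reportTests", "CohortReport", function(x) x@tests)

setMethod("show", "CohortReport", function(object) {
  cat(sprintf("CohortReport: %d metrics x %d periods, reference cohort '%s'\n",
              length(object@metrics),
              length(unique(object@summary$period)), object@reference))
  cat("  use reportTable() for the formatted median (IQR) table\n")
})
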