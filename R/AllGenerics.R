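#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("readingTimes", function(x) standardGeneric("readingTimes"))

#' @rdname accessors
#' @export
setGeneric("glucoseValues", function(x) standardGeneric("glucoseValues"))

#' @rdname accessors
#' @export
setGeneric("nominalInterval", function(x) standardGeneric("nominalInterval"))

#' @rdname accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname accessors
#' @export
setGeneric("windowStart", function(x) standardGeneric("windowStart"))

#' @rdname accessors
#' @export
setGeneric("windowDays", function(x) standardGeneric("windowDays"))

#' @rdname accessors
#' @export
setGeneric("wearFractionOf", function(x) standardGeneric("wearFractionOf"))

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @rdname accessors
#' @export
setGeneric("unmatchedReference", function(x) standardGeneric("unmatchedReference"))

#' @rdname accessors
#' @export
setGeneric("balanceTable", function(x) standardGeneric("balanceTable"))

#' @rdname accessors
#' @export
setGeneric("maxAbsSmdAfter", function(x) standardGeneric("maxAbsSmdAfter"))

#' @rdname accessors
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))

#' @rdname accessors
#' @export
setGeneric("propensityScores", function(x) standardGeneric("propensityScores"))

#' @rdname accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' @rdname accessors
#' @export
setGeneric("latentTraces", function(x) standardGeneric("latentTraces"))

#' @rdname accessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))

#' @rdname accessors
#' @export
setGeneric("reportTests", function(x) standardGeneric("reportTests"))
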