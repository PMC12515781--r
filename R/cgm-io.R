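# Long-format CSV ingestion and serialization.

#' Read long-format CGM data into a cohort object
#'
#' Reads a long CSV (one row per reading) and an optional covariate CSV, snaps
#' timestamps onto the nominal grid, clips glucose to the reportable sensor
#' span of 40--400 mg/dL, drops unparseable rows, and deduplicates repeated
#' grid slots (first occurrence wins). A parse report (rows read, dropped,
#' clipped, duplicates) is stored in the returned cohort's metadata.
#'
#' @param cgmPath path to the reading-level CSV.
#' @param covariatesPath optional path to a per-subject covariate CSV with
#'   columns \code{subject_id}, \code{age_years}, \code{sex}, \code{bmi},
#'   \code{cohort}.
#' @param schema named character map from the roles \code{subject_id},
#'   \code{timestamp}, \code{glucose} to the file's column names.
#' @param interval nominal grid interval in minutes.
#' @param name cohort label for the returned object.
#' @return a \linkS4class{CgmCohort}; \code{covariates(x)} carries the joined
#'   covariates (with \code{sex} recoded 1 = female, 0 = male) and
#'   \code{x@metadata$parseReport} the ingestion counts.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,timestamp,glucose_mgdl",
#'              "S1,2023-03-01T00:00:00,100",
#'              "S1,2023-03-01T00:05:00,105",
#'              "S1,2023-03-01T00:10:00,110"), f)
#' co <- readCgmCsv(f)
#' co@metadata$parseReport
#' @export
readCgmCsv <- function(cgmPath, covariatesPath = NULL,
                       schema = c(subject_id = "subject_id",
                                  timestamp = "timestamp",
                                  glucose = "glucose_mgdl"),
                       interval = 5, name = "ingest") {
  if (!file.exists(cgmPath)) stop("CGM file does not exist: ", cgmPath)
  raw <- utils::read.csv(cgmPath, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (role in c("subject_id", "timestamp", "glucose")) {
    if (!schema[[role]] %in% names(raw))
      stop("missing column: ", schema[[role]])
  }
  nRead <- nrow(raw)
  ids <- as.character(raw[[schema[["subject_id"]]]])
  ts <- raw[[schema[["timestamp"]]]]
  time <- as.POSIXct(rep(NA_real_, length(ts)), origin = "1970-01-01",
                     tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(time)
    if (!any(miss)) break
    time[miss] <- as.POSIXct(strptime(ts[miss], fmt, tz = "UTC"))
  }
  glucose <- suppressWarnings(as.numeric(raw[[schema[["glucose"]]]]))
  bad <- is.na(time) | is.na(glucose) | !nzchar(ids)
  if (nRead > 0 && sum(bad) > nRead / 2)
    stop(sprintf("more than half of the rows failed to parse (%d of %d)",
                 sum(bad), nRead))
  ids <- ids[!bad]; time <- time[!bad]; glucose <- glucose[!bad]

  # Snap to the nearest grid slot; every timestamp is within half an interval
  # of some slot, so snapping never drops rows.
  step <- interval * 60
  time <- as.POSIXct(round(as.numeric(time) / step) * step,
                     origin = "1970-01-01", tz = "UTC")

  nClipped <- sum(glucose < 40 | glucose > 400)
  glucose <- pmin(pmax(glucose, 40), 400)

  ord <- order(ids, time)
  ids <- ids[ord]; time <- time[ord]; glucose <- glucose[ord]
  dup <- duplicated(paste(ids, as.numeric(time)))
  nDup <- sum(dup)
  ids <- ids[!dup]; time <- time[!dup]; glucose <- glucose[!dup]

  traceList <- lapply(split(seq_along(ids), ids), function(ix)
    CgmTrace(ids[ix[1]], time[ix], glucose[ix], interval = interval))

  cov <- data.frame()
  if (!is.null(covariatesPath)) {
    if (!file.exists(covariatesPath))
      stop("covariate file does not exist: ", covariatesPath)
    cov <- utils::read.csv(covariatesPath, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(cov))
      stop("missing column: subject_id (covariate file)")
    if ("age_years" %in% names(cov) && !"age" %in% names(cov))
      cov$age <- cov$age_years
    if ("sex" %in% names(cov) && is.character(cov$sex))
      cov$sex <- as.integer(toupper(substr(cov$sex, 1, 1)) == "F")
    cov <- cov[match(names(traceList), cov$subject_id), , drop = FALSE]
    if (anyNA(cov$subject_id))
      stop("covariate table lacks rows for some subjects: ",
           paste(setdiff(names(traceList), cov$subject_id), collapse = ", "))
    rownames(cov) <- NULL
  }

  report <- list(rows_read = nRead, rows_dropped = sum(bad),
                 rows_clipped = nClipped, duplicates = nDup,
                 subjects = length(traceList))
  CgmCohort(name, traceList, cov, metadata = list(parseReport = report))
}

#' Write a cohort back to the long CSV dialect
#'
#' Inverse of \code{\link{readCgmCsv}}: writing then re-reading any cohort on
#' the grid reproduces identical timestamps and (clipped) glucose values.
#'
#' @param x a \linkS4class{CgmCohort} or a list of \linkS4class{CgmTrace}.
#' @param cgmPath output path for the reading-level CSV.
#' @param covariatesPath optional output path for the covariate CSV.
#' @return invisibly, the reading-level data.frame written.
#' @export
writeCgmCsv <- function(x, cgmPath, covariatesPath = NULL) {
  trs <- if (is(x, "CgmCohort")) x@traces else x
  df <- do.call(rbind, lapply(trs, function(tr)
    data.frame(subject_id = tr@subjectId,
               timestamp = format(tr@time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               glucose_mgdl = format(tr@glucose, trim = TRUE, digits = 15),
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  utils::write.csv(df, cgmPath, row.names = FALSE, quote = FALSE)
  if (!is.null(covariatesPath) && is(x, "CgmCohort") && nrow(x@covariates))
    utils::write.csv(x@covariates, covariatesPath, row.names = FALSE,
                     quote = FALSE)
  invisible(df)
}
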