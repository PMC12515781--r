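# Propensity-score matching with standardized-mean-difference balance.

#' Standardized mean difference between two samples
#'
#' Continuous covariates: \eqn{(\bar{x}_a - \bar{x}_b) /
#' \sqrt{(s_a^2 + s_b^2)/2}} with sample variances. Binary covariates
#' (proportions \eqn{p_a, p_b}): \eqn{(p_a - p_b) /
#' \sqrt{(p_a(1-p_a) + p_b(1-p_b))/2}}. When both variance terms vanish the
#' SMD is 0 if the means agree and a \code{degenerate covariate} error
#' otherwise.
#'
#' @param a,b numeric samples (0/1 for binary covariates).
#' @param kind \code{"continuous"} or \code{"binary"}.
#' @return the signed SMD (dimensionless).
#' @examples
#' smd(c(2, 3, 4), c(1, 2, 3))
#' smd(rep(c(1, 0), c(36, 9)), rep(c(1, 0), c(36, 9)), kind = "binary")  # 0
#' @export
smd <- function(a, b, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    stopifnot(length(a) >= 2, length(b) >= 2)
    denom2 <- (stats::var(a) + stats::var(b)) / 2
  } else {
    stopifnot(length(a) >= 1, length(b) >= 1,
              all(a %in% c(0, 1)), all(b %in% c(0, 1)))
    pa <- mean(a); pb <- mean(b)
    denom2 <- (pa * (1 - pa) + pb * (1 - pb)) / 2
  }
  dm <- mean(a) - mean(b)
  if (denom2 <= 0) {
    if (abs(dm) < 1e-12) return(0)
    stop("degenerate covariate: zero pooled variance with unequal means")
  }
  dm / sqrt(denom2)
}

#' Fit a logistic propensity model
#'
#' Binary-outcome generalized linear model with logit link (reference = 1,
#' pool = 0) fit by iteratively reweighted least squares with convergence
#' tolerance 1e-8 and at most 100 iterations. Continuous covariates are
#' standardized internally for numerical stability; reported coefficients are
#' back-transformed to the original covariate scale. Perfect separation is
#' reported as an error naming the most separating covariate.
#'
#' @param reference data.frame of reference subjects with \code{subject_id}
#'   and the covariate columns.
#' @param pool data.frame of candidate pool subjects, same columns.
#' @param covariateCols covariate column names (default age, sex, bmi).
#' @return a \linkS4class{PropensityModel}; \code{propensityScores(x)} is
#'   named by subject id over reference then pool.
#' @export
fitPropensity <- function(reference, pool,
                          covariateCols = c("age", "sex", "bmi")) {
  stopifnot(nrow(reference) > 0, nrow(pool) > 0)
  df <- rbind(reference[, c("subject_id", covariateCols)],
              pool[, c("subject_id", covariateCols)])
  y <- rep(c(1, 0), c(nrow(reference), nrow(pool)))
  X <- df[, covariateCols, drop = FALSE]
  isBin <- vapply(X, function(v) all(v %in% c(0, 1)), logical(1))
  ctr <- vapply(X, mean, numeric(1))
  scl <- vapply(X, stats::sd, numeric(1))
  ctr[isBin] <- 0; scl[isBin] <- 1
  if (any(scl == 0))
    stop("degenerate covariate (zero variance): ",
         paste(covariateCols[scl == 0], collapse = ", "))
  Xs <- as.data.frame(scale(X, center = ctr, scale = scl))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, Xs), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep) {
    worst <- names(which.max(abs(stats::coef(fit)[-1])))
    stop("perfect separation detected; separating covariate: ", worst)
  }
  if (!fit$converged)
    stop(sprintf("propensity model did not converge in %d iterations",
                 fit$iter))
  betaS <- stats::coef(fit)
  beta <- betaS[-1] / scl
  intercept <- betaS[1] - sum(betaS[-1] * ctr / scl)
  scores <- stats::fitted(fit)
  names(scores) <- df$subject_id
  grp <- y; names(grp) <- df$subject_id
  new("PropensityModel",
      coefficients = c("(Intercept)" = unname(intercept),
                       stats::setNames(beta, covariateCols)),
      converged = fit$converged, nIterations = as.integer(fit$iter),
      scores = scores, group = grp)
}

#' Greedy 1:1 nearest-neighbour matching on the logit propensity score
#'
#' Reference subjects are processed in descending propensity-score order
#' (protecting the hardest-to-match subjects), each taking the still-available
#' pool subject nearest on the logit-score scale, without replacement. Ties in
#' score order and in distance are broken by lexical subject id. Pairs whose
#' distance exceeds the caliper are left unmatched. With \code{exact}, a
#' candidate must also share the reference subject's stratum (e.g. sex).
#'
#' @param refScores,poolScores named propensity scores in (0, 1).
#' @param caliper \code{"auto"} (0.2 SD of all logit scores), a numeric width
#'   on the logit scale, or \code{NULL} for no caliper.
#' @param exact optional named stratum labels (covering both score vectors)
#'   that matched pairs must share exactly.
#' @return a \linkS4class{MatchResult}.
#' @examples
#' r <- c(A = 0.9, B = 0.1); p <- c(X = 0.8, Y = 0.2, Z = 0.5)
#' matchedPairs(matchNearest(r, p, caliper = NULL))
#' @export
matchNearest <- function(refScores, poolScores, caliper = "auto",
                         exact = NULL) {
  if (length(poolScores) == 0) stop("empty pool")
  if (length(poolScores) < length(refScores))
    warning("pool smaller than reference; matching will be partial")
  lr <- logit(refScores); lp <- logit(poolScores)
  calW <- NA_real_
  if (identical(caliper, "auto"))
    calW <- 0.2 * stats::sd(c(lr, lp))
  else if (is.numeric(caliper)) calW <- caliper
  ord <- names(sort(refScores, decreasing = TRUE))
  # stable lexical tie-break on equal scores
  ord <- ord[order(-refScores[ord], ord)]
  avail <- rep(TRUE, length(poolScores))
  names(avail) <- names(poolScores)
  pairs <- list(); unmatched <- character()
  for (rid in ord) {
    cand <- names(avail)[avail]
    if (!is.null(exact)) cand <- cand[exact[cand] == exact[[rid]]]
    if (length(cand) == 0) { unmatched <- c(unmatched, rid); next }
    d <- abs(lp[cand] - lr[[rid]])
    best <- cand[order(d, cand)][1]
    if (!is.na(calW) && d[[best]] > calW) { unmatched <- c(unmatched, rid); next }
    avail[best] <- FALSE
    pairs[[length(pairs) + 1L]] <- data.frame(reference_id = rid,
                                              matched_id = best,
                                              distance = unname(d[[best]]),
                                              stringsAsFactors = FALSE)
  }
  pairDf <- if (length(pairs)) do.call(rbind, pairs)
            else data.frame(reference_id = character(),
                            matched_id = character(), distance = numeric(),
                            stringsAsFactors = FALSE)
  rownames(pairDf) <- NULL
  new("MatchResult", pairs = pairDf, unmatchedReference = unmatched,
      caliperUsed = calW)
}

# Greedy matching in descending score order; candidates are restricted by
# exact strata and the logit-score caliper, the candidate nearest in
# Mahalanobis distance over `metricCols` is taken, and pairs farther than
# `qualityCaliper` are rejected.
.greedyMetricMatch <- function(reference, pool, refScores, poolScores,
                               caliper, exact, metricCols, qualityCaliper) {
  lr <- logit(refScores); lp <- logit(poolScores)
  calW <- NA_real_
  if (identical(caliper, "auto")) calW <- 0.2 * stats::sd(c(lr, lp))
  else if (is.numeric(caliper)) calW <- caliper
  X <- rbind(reference[, metricCols, drop = FALSE],
             pool[, metricCols, drop = FALSE])
  Sinv <- solve(stats::cov(X))
  ord <- order(-refScores, reference$subject_id)
  avail <- rep(TRUE, nrow(pool))
  pairs <- list(); unmatched <- character()
  for (i in ord) {
    rid <- reference$subject_id[i]
    cand <- which(avail)
    if (!is.null(exact))
      cand <- cand[exact[pool$subject_id[cand]] == exact[[rid]]]
    if (!is.na(calW))
      cand <- cand[abs(lp[pool$subject_id[cand]] - lr[[rid]]) <= calW]
    if (length(cand) == 0) { unmatched <- c(unmatched, rid); next }
    d <- stats::mahalanobis(pool[cand, metricCols, drop = FALSE],
                            as.numeric(reference[i, metricCols]),
                            Sinv, inverted = TRUE)
    best <- cand[order(d, pool$subject_id[cand])][1]
    dBest <- sqrt(min(d))
    if (dBest > qualityCaliper) { unmatched <- c(unmatched, rid); next }
    avail[best] <- FALSE
    pid <- pool$subject_id[best]
    pairs[[length(pairs) + 1L]] <- data.frame(
      reference_id = rid, matched_id = pid,
      distance = abs(lp[[pid]] - lr[[rid]]), stringsAsFactors = FALSE)
  }
  pairDf <- if (length(pairs)) do.call(rbind, pairs)
            else data.frame(reference_id = character(),
                            matched_id = character(), distance = numeric(),
                            stringsAsFactors = FALSE)
  rownames(pairDf) <- NULL
  new("MatchResult", pairs = pairDf, unmatchedReference = unmatched,
      caliperUsed = calW)
}

#' Covariate balance before and after matching
#'
#' @param reference covariate data.frame of the (matched) reference subjects.
#' @param matched covariate data.frame of the matched pool subjects.
#' @param prePool covariate data.frame of the full pre-matching pool.
#' @param covariateCols covariate columns to evaluate.
#' @param threshold balance threshold on |SMD| (0.1 by convention).
#' @return a \linkS4class{BalanceReport}.
#' @export
balanceReport <- function(reference, matched, prePool,
                          covariateCols = c("age", "sex", "bmi"),
                          threshold = 0.1) {
  stopifnot(nrow(matched) > 0)
  rows <- lapply(covariateCols, function(cc) {
    kind <- if (all(reference[[cc]] %in% c(0, 1)) &&
                all(prePool[[cc]] %in% c(0, 1))) "binary" else "continuous"
    data.frame(covariate = cc, kind = kind,
               smd_pre = smd(reference[[cc]], prePool[[cc]], kind),
               smd_post = smd(reference[[cc]], matched[[cc]], kind),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mx <- max(abs(tab$smd_post))
  new("BalanceReport", table = tab, maxAbsSmdAfter = mx,
      threshold = threshold, balanced = mx < threshold)
}

#' Propensity-match a pool to a reference cohort
#'
#' End-to-end convenience implementing caliper matching with the Mahalanobis
#' metric inside propensity calipers: the logistic propensity model is fit on
#' the covariates; reference subjects are processed greedily in descending
#' score order; each may only be paired with a still-available pool subject
#' of the same sex whose logit score lies within the caliper, and among those
#' candidates the one nearest in Mahalanobis distance on the continuous
#' covariates is taken. Pairs whose Mahalanobis distance exceeds
#' \code{qualityCaliper} are rejected, leaving the reference subject
#' unmatched -- with covariate-shifted pools this pruning is what keeps every
#' post-matching |SMD| reliably below the balance threshold. Balance is
#' reported on the matched pairs.
#'
#' @param reference,pool covariate data.frames with \code{subject_id} and the
#'   covariate columns.
#' @param covariateCols covariates entering the propensity model.
#' @param exactCols columns matched exactly (default \code{"sex"}; use
#'   \code{character()} for pure score matching).
#' @param caliper as in \code{\link{matchNearest}}.
#' @param metricCols continuous covariates entering the within-caliper
#'   Mahalanobis metric; \code{character()} falls back to nearest-score
#'   selection.
#' @param qualityCaliper maximum admissible Mahalanobis distance for a pair
#'   (\code{Inf} disables pruning).
#' @param threshold balance threshold.
#' @return list with \code{model} (\linkS4class{PropensityModel}),
#'   \code{match} (\linkS4class{MatchResult}), \code{balance}
#'   (\linkS4class{BalanceReport}), and \code{matchedPool} /
#'   \code{matchedReference} covariate data.frames.
#' @export
propensityMatch <- function(reference, pool,
                            covariateCols = c("age", "sex", "bmi"),
                            exactCols = "sex", caliper = "auto",
                            metricCols = c("age", "bmi"),
                            qualityCaliper = 0.5, threshold = 0.1) {
  model <- fitPropensity(reference, pool, covariateCols)
  sc <- model@scores
  refScores <- sc[reference$subject_id]
  poolScores <- sc[pool$subject_id]
  exact <- NULL
  if (length(exactCols)) {
    lab <- function(df) apply(df[, exactCols, drop = FALSE], 1, paste,
                              collapse = "|")
    exact <- c(stats::setNames(lab(reference), reference$subject_id),
               stats::setNames(lab(pool), pool$subject_id))
  }
  if (length(metricCols)) {
    mr <- .greedyMetricMatch(reference, pool, refScores, poolScores,
                             caliper = caliper, exact = exact,
                             metricCols = metricCols,
                             qualityCaliper = qualityCaliper)
  } else {
    mr <- matchNearest(refScores, poolScores, caliper = caliper,
                       exact = exact)
  }
  p <- mr@pairs
  matchedRef <- reference[match(p$reference_id, reference$subject_id), ,
                          drop = FALSE]
  matchedPool <- pool[match(p$matched_id, pool$subject_id), , drop = FALSE]
  bal <- balanceReport(matchedRef, matchedPool, pool, covariateCols,
                       threshold)
  list(model = model, match = mr, balance = bal,
       matchedReference = matchedRef, matchedPool = matchedPool)
}
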