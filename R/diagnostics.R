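#' Round half away from zero
#'
#' Table-style rounding: exact halves round up in magnitude (89.05 -> 89.1),
#' unlike \code{round()}'s round-half-even. Used for all percentages
#' reported to one decimal.
#'
#' @param x numeric.
#' @param digits decimal places, default 1.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from the beta-quantile construction:
#' lower = qbeta(alpha/2; k, n-k+1) (0 when k = 0),
#' upper = qbeta(1-alpha/2; k+1, n-k) (1 when k = n). Equivalent to
#' inverting the binomial tail probabilities; guaranteed coverage at least
#' the nominal level.
#'
#' @param k successes (vectorised).
#' @param n trials.
#' @param level confidence level, default 0.95.
#' @return matrix with columns \code{low}, \code{high} (proportions).
#' @examples
#' clopperPearson(195, 219)  # 0.841 - 0.929
#' @export
clopperPearson <- function(k, n, level = 0.95) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(k < 0) || any(k > n)) stop("'k' must lie in [0, n]")
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(low = low, high = high)
}

#' Confusion table from a labeled cohort
#'
#' Cross-tabulates a binary classifier column against the \code{eligible}
#' label: tp = eligible and positive, fp = non-eligible positive, fn =
#' eligible negative, tn = non-eligible negative.
#'
#' @param records data.frame with a logical \code{eligible} column, a
#'   \code{patient_id} column, and the classifier column.
#' @param classifierField name of the logical classifier column, e.g.
#'   \code{"hhm_positive"} or \code{"extend_positive"}.
#' @return a \linkS4class{ConfusionTable}.
#' @export
confusionFromCohort <- function(records, classifierField) {
  if (NROW(records) == 0L) stop("empty cohort")
  if (!"eligible" %in% names(records)) stop("records lack 'eligible'")
  if (!classifierField %in% names(records))
    stop("records lack classifier column '", classifierField, "'")
  calls <- records[[classifierField]]
  bad <- is.na(calls) | is.na(records$eligible)
  if (any(bad)) {
    ids <- if ("patient_id" %in% names(records))
      records$patient_id[bad] else which(bad)
    stop("missing classifier/eligibility values for: ",
         paste(ids, collapse = ", "))
  }
  e <- records$eligible
  confusionTable(tp = sum(e & calls), fp = sum(!e & calls),
                 fn = sum(e & !calls), tn = sum(!e & !calls))
}

# Hanley-McNeil standard error of an AUC with na positives, nn negatives
.aucSE <- function(auc, na, nn) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (na - 1) * (q1 - auc^2) +
          (nn - 1) * (q2 - auc^2)) / (na * nn))
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp), negative predictive value tn/(tn+fn), each with an exact
#' Clopper-Pearson interval on its own numerator/denominator, and the AUC of
#' the binary test, (sensitivity + specificity)/2, with a Hanley-McNeil
#' normal-approximation interval (truncated to [0, 1]). All values are
#' reported in percent. A metric whose denominator is zero is returned as
#' NA rather than fabricated.
#'
#' @param ct a \linkS4class{ConfusionTable}.
#' @param level confidence level, default 0.95.
#' @return data.frame with columns \code{metric}, \code{estimate},
#'   \code{ciLow}, \code{ciHigh} (percent, unrounded).
#' @examples
#' accuracyMetrics(confusionTable(195, 8, 24, 20))
#' @export
accuracyMetrics <- function(ct, level = 0.95) {
  stopifnot(is(ct, "ConfusionTable"))
  one <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- clopperPearson(k, n, level)
    c(k / n, ci[1, "low"], ci[1, "high"]) * 100
  }
  sens <- one(ct@tp, ct@tp + ct@fn)
  spec <- one(ct@tn, ct@tn + ct@fp)
  ppv <- one(ct@tp, ct@tp + ct@fp)
  npv <- one(ct@tn, ct@tn + ct@fn)
  auc <- rep(NA_real_, 3)
  if (!is.na(sens[1]) && !is.na(spec[1])) {
    a <- (sens[1] + spec[1]) / 2 / 100
    se <- .aucSE(a, ct@tp + ct@fn, ct@tn + ct@fp)
    z <- qnorm(1 - (1 - level) / 2)
    auc <- c(a, max(0, a - z * se), min(1, a + z * se)) * 100
  }
  out <- rbind(sensitivity = sens, specificity = spec, ppv = ppv,
               npv = npv, auc = auc)
  data.frame(metric = rownames(out), estimate = out[, 1],
             ciLow = out[, 2], ciHigh = out[, 3], row.names = NULL)
}

#' Compare two proportions
#'
#' Pearson chi-square without continuity correction by default (the SPSS
#' "Pearson Chi-Square" convention); Fisher's exact test by flag.
#'
#' @param k1,n1 successes/trials in group 1.
#' @param k2,n2 successes/trials in group 2.
#' @param method "chisq" (default) or "fisher".
#' @return two-sided p-value.
#' @examples
#' compareProportions(190, 197, 5, 22)  # < 0.001
#' @export
compareProportions <- function(k1, n1, k2, n2,
                               method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (any(c(k1, k2) < 0) || k1 > n1 || k2 > n2 || n1 < 1 || n2 < 1)
    stop("invalid counts")
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin is zero")
  if (method == "chisq")
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  else
    fisher.test(tab)$p.value
}

#' Compare two continuous samples
#'
#' Student's t-test (equal variances, the SPSS default) or the
#' Mann-Whitney U-test (normal approximation without continuity correction
#' in the presence of ties), two-sided.
#'
#' @param x,y numeric samples, each of length >= 2 (NAs dropped).
#' @param method "t_test" or "mann_whitney".
#' @return two-sided p-value.
#' @export
compareContinuous <- function(x, y, method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (method == "t_test") {
    if (var(x) == 0 && var(y) == 0)
      stop("degenerate t-test: both groups have zero variance")
    t.test(x, y, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(wilcox.test(x, y, correct = FALSE)$p.value)
  }
}

#' Baseline-characteristics summary of a labeled cohort
#'
#' Per-group (eligible vs. not eligible) descriptive statistics in the
#' layout of a baseline table: mean (SD), median (IQR) and missing counts
#' for numeric covariates; count (percent of non-missing) and missing
#' counts for logical ones; with a group-comparison p-value (t-test or
#' Mann-Whitney for numeric, chi-square for logical).
#'
#' @param records data.frame with logical \code{eligible} plus covariates.
#' @param covariates character vector of covariate column names; defaults to
#'   every column except id/label/bookkeeping columns.
#' @param continuousMethod "t_test" or "mann_whitney" for numeric covariates.
#' @return data.frame, one row per covariate.
#' @export
cohortSummary <- function(records, covariates = NULL,
                          continuousMethod = c("t_test", "mann_whitney")) {
  continuousMethod <- match.arg(continuousMethod)
  if (!"eligible" %in% names(records)) stop("records lack 'eligible'")
  if (is.null(covariates)) {
    skip <- c("patient_id", "eligible", "stratum", "phantom_seed",
              "lesion_scale", "matched_lesion", "eligible_expected")
    covariates <- setdiff(names(records), skip)
  }
  g1 <- records[records$eligible %in% TRUE, , drop = FALSE]
  g2 <- records[records$eligible %in% FALSE, , drop = FALSE]
  rows <- lapply(covariates, function(cv) {
    x1 <- g1[[cv]]; x2 <- g2[[cv]]
    miss1 <- sum(is.na(x1)); miss2 <- sum(is.na(x2))
    v1 <- x1[!is.na(x1)]; v2 <- x2[!is.na(x2)]
    if (is.numeric(x1)) {
      p <- tryCatch(compareContinuous(v1, v2, continuousMethod),
                    error = function(e) NA_real_)
      data.frame(covariate = cv, type = "continuous",
                 eligible_summary = sprintf("%.1f (%s)", mean(v1),
                   if (length(v1) > 1) sprintf("%.1f", sd(v1)) else "NA"),
                 noneligible_summary = sprintf("%.1f (%s)", mean(v2),
                   if (length(v2) > 1) sprintf("%.1f", sd(v2)) else "NA"),
                 eligible_median_iqr = sprintf("%.1f (%.1f)", median(v1),
                                               IQR(v1)),
                 noneligible_median_iqr = sprintf("%.1f (%.1f)", median(v2),
                                                  IQR(v2)),
                 missing_eligible = miss1, missing_noneligible = miss2,
                 p_value = p)
    } else {
      b1 <- as.logical(v1); b2 <- as.logical(v2)
      p <- tryCatch(compareProportions(sum(b1), length(b1),
                                       sum(b2), length(b2)),
                    error = function(e) NA_real_)
      data.frame(covariate = cv, type = "categorical",
                 eligible_summary = sprintf("%d (%.1f)", sum(b1),
                                            100 * mean(b1)),
                 noneligible_summary = sprintf("%d (%.1f)", sum(b2),
                                               100 * mean(b2)),
                 eligible_median_iqr = NA_character_,
                 noneligible_median_iqr = NA_character_,
                 missing_eligible = miss1, missing_noneligible = miss2,
                 p_value = p)
    }
  })
  do.call(rbind, rows)
}

#' Published cohort contingency structure
#'
#' The per-patient record table implied by the published multicenter
#' cohort's stratum counts: 197 patients within 4.5 h of onset (190
#' HHM-positive, 88 EXTEND-positive), 22 late presenters eligible by
#' automated mismatch (all EXTEND-positive, 5 HHM-positive) and 28 late
#' non-eligible patients (8 HHM-positive, none EXTEND-positive). Only the
#' marginal classifier counts per stratum are published; the within-stratum
#' joint assignment of the two classifiers is arbitrary and irrelevant to
#' any per-classifier confusion table. Onset times are not published per
#' patient and are returned as NA.
#'
#' @return data.frame with 247 rows: \code{patient_id}, \code{stratum},
#'   \code{onset_to_ct_h} (NA), \code{eligible}, \code{hhm_positive},
#'   \code{extend_positive}.
#' @export
referenceCohort <- function() {
  strat <- rep(c("within_window", "late_mismatch", "late_no_mismatch"),
               c(197L, 22L, 28L))
  hhm <- c(rep(c(TRUE, FALSE), c(190L, 7L)),
           rep(c(TRUE, FALSE), c(5L, 17L)),
           rep(c(TRUE, FALSE), c(8L, 20L)))
  ext <- c(rep(c(TRUE, FALSE), c(88L, 109L)),
           rep(TRUE, 22L), rep(FALSE, 28L))
  data.frame(patient_id = sprintf("P%03d", seq_along(strat)),
             stratum = strat, onset_to_ct_h = NA_real_,
             eligible = strat != "late_no_mismatch",
             hhm_positive = hhm, extend_positive = ext,
             stringsAsFactors = FALSE)
}
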