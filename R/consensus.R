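#' @include ensemble.R
NULL

#' Model-by-patient vote matrix
#'
#' Entry (m, i) is 1 when model m labels patient i `SASP_H` under its frozen
#' cutoff, 0 otherwise; the matrix is complete by construction.
#'
#' @param models list of [RidgeCoxModel-class] or [ModelRecord-class].
#' @param cohort a [SASPCohort-class] (or patients x analytes matrix).
#' @return binary matrix, models x patients, with model ids as row names
#'   and patient ids as column names.
#' @export
buildVoteMatrix <- function(models, cohort) {
  if (!length(models)) stop("no models supplied")
  models <- lapply(models, function(m) if (is(m, "ModelRecord")) m@model else m)
  votes <- t(vapply(models,
                    function(m) as.numeric(dichotomize(m, cohort) == "SASP_H"),
                    numeric(if (is(cohort, "SASPCohort")) ncol(cohort) else nrow(cohort))))
  rownames(votes) <- vapply(models, function(m) as.character(m@modelId), character(1))
  colnames(votes) <- if (is(cohort, "SASPCohort")) patientData(cohort)$id
                     else rownames(cohort)
  votes
}

#' Plurality-voting consensus classification
#'
#' Per patient, `high_fraction` is the fraction of models voting `SASP_H`.
#' The binary rule labels a patient H iff more than 50% of models vote H;
#' the ternary rule labels H above 75%, L below 25%, and M otherwise.
#' Boundary fractions (exactly 0.5 / 0.75 / 0.25) resolve downward: the
#' thresholds are strict, so ties fall to L or M respectively.
#'
#' @param votes binary models x patients matrix from [buildVoteMatrix()].
#' @return data.frame with columns `patient`, `high_fraction`, `binary`
#'   (factor L/H) and `ternary` (factor L/M/H).
#' @export
consensusVote <- function(votes) {
  if (!nrow(votes)) stop("need at least one model")
  f <- colMeans(votes)
  data.frame(
    patient = colnames(votes),
    high_fraction = unname(f),
    binary = factor(ifelse(f > 0.5, "H", "L"), levels = c("L", "H")),
    ternary = factor(ifelse(f > 0.75, "H", ifelse(f < 0.25, "L", "M")),
                     levels = c("L", "M", "H")),
    stringsAsFactors = FALSE)
}

#' Classification-confidence summary
#'
#' A patient's confidence is the fraction of models agreeing with their
#' majority class, `max(high_fraction, 1 - high_fraction)`. Reports the
#' fraction of patients at or above the confidence threshold (75% by
#' default), the fraction below, and the per-class breakdown under the
#' ternary rule.
#'
#' @param assignments data.frame from [consensusVote()].
#' @param threshold confidence threshold (default 0.75).
#' @return list: `high_confidence`, `low_confidence` (summing to 1),
#'   `by_class` (table of ternary labels).
#' @export
confidenceSummary <- function(assignments, threshold = 0.75) {
  if (!nrow(assignments)) stop("empty assignments")
  conf <- pmax(assignments$high_fraction, 1 - assignments$high_fraction)
  hc <- mean(conf >= threshold)
  list(high_confidence = hc, low_confidence = 1 - hc,
       by_class = table(assignments$ternary))
}
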