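#' @include SASPsurv-package.R
NULL

.COHORT_LABELS <- c("RTBT2", "RTBT3", "RT3")

#' Cohort container: analyte matrix plus clinical and survival covariates
#'
#' `SASPCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `log2` assay holding analytes (rows) by patients (columns), and
#' clinical covariates in `colData`: `id`, `age`, `stage` (`"II"`/`"III"`),
#' `treatment` (`"EBRT"`/`"EBRT+BT"`), follow-up `time` in years, `event`
#' (1 = disease-specific death) and, for simulated cohorts, the hidden latent
#' factor `latent_z`. The cohort label ties stage and treatment together:
#' RTBT2 = stage II, EBRT+BT; RTBT3 = stage III, EBRT+BT; RT3 = stage III,
#' EBRT alone.
#'
#' @slot label character; one of `"RTBT2"`, `"RTBT3"`, `"RT3"`.
#' @export
setClass("SASPCohort",
  contains = "SummarizedExperiment",
  representation(label = "character")
)

setValidity("SASPCohort", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !object@label %in% .COHORT_LABELS)
    msg <- c(msg, sprintf("label must be one of %s",
                          paste(.COHORT_LABELS, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  need <- c("id", "stage", "treatment", "time", "event")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, sprintf("colData must contain %s", paste(need, collapse = ", ")))
    return(if (length(msg)) msg else TRUE)
  }
  if (ncol(object) > 0L) {
    exp_stage <- if (object@label == "RTBT2") "II" else "III"
    exp_trt <- if (object@label == "RT3") "EBRT" else "EBRT+BT"
    if (!all(cd$stage == exp_stage))
      msg <- c(msg, sprintf("all %s patients must be stage %s", object@label, exp_stage))
    if (!all(cd$treatment == exp_trt))
      msg <- c(msg, sprintf("all %s patients must have treatment %s", object@label, exp_trt))
    if (any(cd$time <= 0)) msg <- c(msg, "all follow-up times must be > 0")
    if (!all(cd$event %in% c(0, 1))) msg <- c(msg, "event must be 0/1")
    if (anyDuplicated(cd$id)) msg <- c(msg, "patient ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' L2-penalized proportional-hazards fit
#'
#' Coefficients live on the standardized-covariate scale; the training
#' centering/scaling is frozen in the object and reapplied verbatim to any
#' new data by [linearPredictor()].
#'
#' @slot beta named numeric; penalized coefficients (standardized scale).
#' @slot lambda numeric; L2 penalty weight (objective
#'   `-logPL(beta) + lambda/2 * ||beta||^2`).
#' @slot center,scale named numeric; frozen training standardization.
#' @slot loglik numeric; unpenalized partial log-likelihood at the optimum.
#' @slot converged logical.
#' @slot ties character; `"efron"` or `"breslow"`.
#' @slot family character; `"cox"` or `"binomial"` (event-by-horizon logistic).
#' @slot cvCurve `NULL` or a data.frame with columns `lambda`, `cv_deviance`
#'   when the penalty was selected by cross-validation.
#' @export
setClass("RidgeCoxFit",
  representation(beta = "numeric", lambda = "numeric", center = "numeric",
                 scale = "numeric", loglik = "numeric", converged = "logical",
                 ties = "character", family = "character", cvCurve = "ANY")
)

setValidity("RidgeCoxFit", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (!all(is.finite(object@beta))) msg <- c(msg, "beta must be finite")
  if (length(object@beta) != length(object@center) ||
      length(object@beta) != length(object@scale))
    msg <- c(msg, "beta, center and scale must have equal length")
  if (!object@ties %in% c("efron", "breslow")) msg <- c(msg, "invalid ties")
  if (!object@family %in% c("cox", "binomial")) msg <- c(msg, "invalid family")
  if (length(msg)) msg else TRUE
})

#' One ensemble member: a ridge score with a frozen dichotomization cutoff
#'
#' @slot modelId integer; the index of the train/test split the model came from.
#' @slot proteins character; analytes entering the score.
#' @slot fit [RidgeCoxFit-class]; oriented so that scores above the cutoff
#'   carry training hazard ratio >= 1.
#' @slot cutoffPercentile numeric; percent of training patients labeled low
#'   (40 reproduces the 40th-percentile rule).
#' @slot cutoffValue numeric; the frozen score cutoff (order-statistic
#'   percentile of the oriented training scores).
#' @slot orientationFlipped logical; TRUE if coefficients were negated so the
#'   high-score group is the high-risk group.
#' @slot trainLabel character; label of the training cohort.
#' @export
setClass("RidgeCoxModel",
  representation(modelId = "integer", proteins = "character",
                 fit = "RidgeCoxFit", cutoffPercentile = "numeric",
                 cutoffValue = "numeric", orientationFlipped = "logical",
                 trainLabel = "character")
)

setValidity("RidgeCoxModel", function(object) {
  msg <- character()
  if (object@cutoffPercentile <= 0 || object@cutoffPercentile >= 100)
    msg <- c(msg, "cutoffPercentile must be in (0, 100)")
  if (!setequal(object@proteins, names(object@fit@beta)))
    msg <- c(msg, "proteins must match the fit's coefficient names")
  if (length(msg)) msg else TRUE
})

#' Audit trail for one ensemble member
#'
#' @slot model [RidgeCoxModel-class].
#' @slot splitEval list with `train` and `test` elements (hr, ci_lo, ci_hi,
#'   p, p_logrank, n, flagged).
#' @slot bootstrap list; see [bootstrapValidate()] (empty until run).
#' @slot external data.frame of per-cohort validation rows (empty until run).
#' @export
setClass("ModelRecord",
  representation(model = "RidgeCoxModel", splitEval = "list",
                 bootstrap = "list", external = "data.frame")
)

setValidity("ModelRecord", function(object) {
  msg <- character()
  if (nrow(object@external) &&
      object@model@trainLabel %in% object@external$cohort)
    msg <- c(msg, "external validation cohorts must exclude the training cohort")
  if (length(object@bootstrap)) {
    b <- object@bootstrap
    if (sum(b$bins) != b$n_boot)
      msg <- c(msg, "bootstrap p-value bins must sum to n_boot")
  }
  if (length(msg)) msg else TRUE
})
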