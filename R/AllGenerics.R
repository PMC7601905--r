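#' @include AllClasses.R
NULL

#' Cohort label accessor
#' @param x a [SASPCohort-class]
#' @return the cohort label, one of `"RTBT2"`, `"RTBT3"`, `"RT3"`
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))

#' @rdname cohortLabel
#' @export
setMethod("cohortLabel", "SASPCohort", function(x) x@label)

#' Patients-by-analytes log2 matrix
#'
#' Returns the assay transposed to the patients x analytes orientation used
#' by the modeling functions, with patient ids as row names.
#'
#' @param x a [SASPCohort-class]
#' @return numeric matrix, patients x analytes
#' @export
setGeneric("analyteMatrix", function(x) standardGeneric("analyteMatrix"))

#' @rdname analyteMatrix
#' @export
setMethod("analyteMatrix", "SASPCohort", function(x) {
  m <- t(SummarizedExperiment::assay(x, "log2"))
  rownames(m) <- SummarizedExperiment::colData(x)$id
  m
})

#' Clinical covariates and survival outcome as a data.frame
#' @param x a [SASPCohort-class]
#' @return data.frame with one row per patient
#' @export
setGeneric("patientData", function(x) standardGeneric("patientData"))

#' @rdname patientData
#' @export
setMethod("patientData", "SASPCohort", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Per-patient risk score from a fitted model
#'
#' Applies the frozen training standardization (never re-derived on new
#' data) and the stored coefficients: `score = beta . (x - center) / scale`.
#' For a [RidgeCoxModel-class] the coefficients are already oriented so that
#' higher scores mean higher hazard.
#'
#' @param fit a [RidgeCoxFit-class] or [RidgeCoxModel-class]
#' @param newdata a [SASPCohort-class] or a patients x covariates matrix
#'   carrying all covariates of the fit
#' @return named numeric vector of scores
#' @export
setGeneric("linearPredictor", function(fit, newdata) standardGeneric("linearPredictor"))

setMethod("show", "SASPCohort", function(object) {
  cat(sprintf("SASPCohort '%s': %d patients, %d analytes, %d events\n",
              object@label, ncol(object), nrow(object),
              sum(SummarizedExperiment::colData(object)$event)))
  callNextMethod()
})

setMethod("show", "RidgeCoxFit", function(object) {
  cat(sprintf("RidgeCoxFit (%s, ties=%s): %d covariates, lambda=%.4g%s\n",
              object@family, object@ties, length(object@beta), object@lambda,
              if (!is.null(object@cvCurve)) " (CV-selected)" else ""))
  print(round(object@beta, 4))
})

setMethod("show", "RidgeCoxModel", function(object) {
  cat(sprintf(
    "RidgeCoxModel #%d [%s]: %d proteins, low/high cutoff at the %gth percentile (score %.4g)%s\n",
    object@modelId, object@trainLabel, length(object@proteins),
    object@cutoffPercentile, object@cutoffValue,
    if (object@orientationFlipped) ", orientation flipped" else ""))
})

setMethod("show", "ModelRecord", function(object) {
  show(object@model)
  se <- object@splitEval
  if (length(se))
    cat(sprintf("  train HR %.2f (p=%.3g), test HR %.2f (p=%.3g)\n",
                se$train$hr, se$train$p, se$test$hr, se$test$p))
  if (length(object@bootstrap))
    cat(sprintf("  bootstrap: mean HR %.2f, pass=%s\n",
                object@bootstrap$mean_hr, object@bootstrap$pass))
  if (nrow(object@external))
    cat(sprintf("  external: %s\n",
                paste(sprintf("%s HR %.2f (p=%.3g)", object@external$cohort,
                              object@external$hr, object@external$p),
                      collapse = "; ")))
})
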