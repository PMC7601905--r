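#' @include consensus.R
NULL

#' Ensemble-size multiple-testing adjustment
#'
#' Bonferroni multiplication of each raw p-value by the number of models,
#' deliberately NOT capped at 1 by default so that the adjusted values match
#' the published convention (adjusted p-values above 1 are reported as-is).
#' A capped Bonferroni and Holm are available.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param nModels number of models compared (>= 1).
#' @param method `"bonferroni_uncapped"` (default), `"bonferroni"` (capped
#'   at 1) or `"holm"` (applied across the supplied vector).
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(p, nModels,
                          method = c("bonferroni_uncapped", "bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1), nModels >= 1)
  switch(method,
         bonferroni_uncapped = p * nModels,
         bonferroni = pmin(p * nModels, 1),
         holm = p.adjust(p, method = "holm", n = max(nModels, length(p))))
}

.stage3_pool <- function(cohorts) {
  if (is(cohorts, "SASPCohort")) cohorts <- list(cohorts)
  pool <- .pool_cohorts(cohorts)
  if (!all(pool$patients$stage == "III"))
    stop("stratified brachytherapy analysis requires stage III patients only")
  if (length(unique(pool$patients$treatment)) < 2)
    stop("need both treatment arms (EBRT and EBRT+BT)")
  pool
}

# one stratum row: no-BT vs BT Cox (no-BT exposed, so HR > 1 = BT benefit)
.bt_stratum_row <- function(stratum, time, event, no_bt, ties) {
  n_bt <- sum(!no_bt); n_nobt <- sum(no_bt)
  if (n_bt == 0 || n_nobt == 0 || sum(event) == 0) {
    return(data.frame(stratum = stratum, n_bt = n_bt, n_nobt = n_nobt,
                      hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, p_logrank = NA_real_, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  fit <- suppressWarnings(coxFit(time, event, cbind(no_bt = as.numeric(no_bt)),
                                 ties = ties))
  lr <- logrankTest(time, event, no_bt)
  data.frame(stratum = stratum, n_bt = n_bt, n_nobt = n_nobt,
             hr = unname(fit$hr["no_bt"]), ci_lo = unname(fit$ci_lo["no_bt"]),
             ci_hi = unname(fit$ci_hi["no_bt"]), p = unname(fit$p["no_bt"]),
             p_logrank = lr$p, flagged = !fit$converged,
             stringsAsFactors = FALSE)
}

#' Brachytherapy effect within SASP strata
#'
#' Pools the stage III cohorts, labels every patient with either one model's
#' frozen-cutoff dichotomization or a supplied consensus classification, and
#' compares survival without vs with brachytherapy inside each stratum
#' (two-group Cox with no-BT as the exposed arm, so HR > 1 means
#' brachytherapy benefit). Consensus mode adds the M stratum of the ternary
#' rule. Strata with a single treatment arm are flagged without an HR.
#' `adj_p` multiplies the raw p by `nModels` (uncapped Bonferroni).
#'
#' @param cohorts stage III [SASPCohort-class] objects (e.g. RTBT3 + RT3).
#' @param labeler a [RidgeCoxModel-class], or a factor/character vector of
#'   per-patient labels (`SASP_L`/`SASP_M`/`SASP_H` or `L`/`M`/`H`) named by
#'   patient id (e.g. the ternary column of [consensusVote()]).
#' @param nModels multiplier for the adjusted p (default 1 = no adjustment).
#' @param ties tie correction.
#' @return data.frame with one row per stratum: counts per arm, HR, 95% CI,
#'   Wald and log-rank p, `adj_p`.
#' @export
stratifiedBtEffect <- function(cohorts, labeler, nModels = 1,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  pool <- .stage3_pool(cohorts)
  labels <- if (is(labeler, "RidgeCoxModel")) {
    as.character(dichotomize(labeler, pool$analytes))
  } else {
    lab <- setNames(as.character(labeler), names(labeler))
    lab <- sub("^([LMH])$", "SASP_\\1", lab)
    miss <- setdiff(pool$patients$id, names(lab))
    if (length(miss)) stop("labels missing for ", length(miss), " patients")
    unname(lab[pool$patients$id])
  }
  no_bt <- pool$patients$treatment == "EBRT"
  strata <- intersect(c("SASP_L", "SASP_M", "SASP_H"), unique(labels))
  out <- do.call(rbind, lapply(strata, function(s) {
    i <- labels == s
    .bt_stratum_row(s, pool$patients$time[i], pool$patients$event[i],
                    no_bt[i], ties)
  }))
  out$adj_p <- out$p * nModels
  out
}

#' Per-model brachytherapy table across an ensemble
#'
#' Applies [stratifiedBtEffect()] for each model, with the Bonferroni
#' multiplier equal to the number of models, mirroring the per-model
#' published layout (`model_id`, stratum, counts, HR, CI, p, adjusted p).
#'
#' @param models list of [RidgeCoxModel-class] or [ModelRecord-class].
#' @param cohorts stage III cohorts.
#' @param ties tie correction.
#' @export
btEffectTable <- function(models, cohorts, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  models <- lapply(models, function(m) if (is(m, "ModelRecord")) m@model else m)
  do.call(rbind, lapply(models, function(m) {
    rows <- stratifiedBtEffect(cohorts, m, nModels = length(models), ties = ties)
    cbind(model_id = m@modelId, rows)
  }))
}

#' Survival summaries for stage x SASP x treatment categories
#'
#' Builds Kaplan-Meier curves and 1-/5-year survival for every
#' cohort-by-SASP-class category (e.g. `RTBT2_L`, `RT3_H`) under a consensus
#' labeling, plus an ordering report across categories by 5-year survival.
#' Empty categories are skipped.
#'
#' @param cohorts list of [SASPCohort-class] objects.
#' @param labels per-patient labels named by patient id (as in
#'   [stratifiedBtEffect()]).
#' @param horizon time of the late survival summary (default 5 years).
#' @return list: `categories` (data.frame `category`, `n`, `events`,
#'   `surv1`, `surv_horizon`, ordered best to worst), `curves` (named list
#'   of `kmCurve`).
#' @export
multifactorStrata <- function(cohorts, labels, horizon = 5) {
  if (is(cohorts, "SASPCohort")) cohorts <- list(cohorts)
  lab <- setNames(as.character(labels), names(labels))
  lab <- sub("^SASP_", "", lab)
  curves <- list()
  rows <- list()
  for (co in cohorts) {
    pd <- patientData(co)
    miss <- setdiff(pd$id, names(lab))
    if (length(miss)) stop("labels missing for ", length(miss), " patients")
    cls <- lab[pd$id]
    for (s in intersect(c("L", "M", "H"), unique(cls))) {
      i <- cls == s
      cat_name <- paste0(cohortLabel(co), "_", s)
      km <- kmEstimate(pd$time[i], pd$event[i])
      curves[[cat_name]] <- km
      rows[[cat_name]] <- data.frame(
        category = cat_name, n = sum(i), events = sum(pd$event[i]),
        surv1 = kmSurvivalAt(km, 1), surv_horizon = kmSurvivalAt(km, horizon),
        stringsAsFactors = FALSE)
    }
  }
  categories <- do.call(rbind, rows)
  categories <- categories[order(-categories$surv_horizon), ]
  rownames(categories) <- NULL
  list(categories = categories, curves = curves)
}
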