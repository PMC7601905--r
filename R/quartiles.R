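#' @include survival-engine.R
NULL

#' Assign patients to analyte quartiles
#'
#' Cutpoints are the 25th/50th/75th percentiles computed by linear
#' interpolation between order statistics (`quantile` type 7), with
#' lower-closed assignment: a value equal to a cutpoint falls in the lower
#' quartile. With 578 distinct values this reproduces the tie-free count
#' pattern 145/144/144/145; heavy ties can make counts unequal, but they
#' always sum to the number of patients.
#'
#' @param values per-patient analyte levels (>= 8 non-missing).
#' @return list of class `quartileAssignment`: `labels` (factor Q1-Q4),
#'   `counts`, `cutpoints`.
#' @export
assignQuartiles <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 8) stop("need at least 8 non-missing values")
  if (length(unique(v)) == 1) stop("all values identical: quartiles undefined")
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  idx <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  labels <- factor(paste0("Q", idx), levels = paste0("Q", 1:4))
  structure(list(labels = labels,
                 counts = table(labels),
                 cutpoints = setNames(q, c("p25", "p50", "p75"))),
            class = "quartileAssignment")
}

.pool_cohorts <- function(datasets) {
  if (is(datasets, "SASPCohort")) datasets <- list(datasets)
  pd <- do.call(rbind, lapply(datasets, function(d) {
    cbind(patientData(d)[, c("id", "stage", "treatment", "time", "event")],
          cohort = cohortLabel(d))
  }))
  am <- do.call(rbind, lapply(datasets, analyteMatrix))
  list(patients = pd, analytes = am, pooled = length(datasets) > 1,
       label = if (length(datasets) > 1) "all" else cohortLabel(datasets[[1]]))
}

#' Quartile Cox contrasts for one protein
#'
#' One proportional-hazards fit with indicator covariates for quartiles
#' Q2-Q4 (Q1 reference). When the input pools heterogeneous cohorts, stage
#' (III vs II) and treatment (no-BT vs BT) enter as adjustment covariates;
#' within a single stage/treatment-homogeneous cohort they are constant and
#' omitted. Quartiles without events yield finite but flagged estimates.
#'
#' @param datasets a [SASPCohort-class] or list of them (pooled).
#' @param protein analyte name.
#' @param adjust `NULL` for the automatic rule above, otherwise a character
#'   subset of `c("stage", "treatment")`.
#' @param ties tie correction for the Cox fit.
#' @return one-row data.frame of class `quartileHRRow` with per-quartile
#'   n, HR, CI, p, plus `flagged` (comma-separated quartiles with no events).
#' @export
quartileCox <- function(datasets, protein, adjust = NULL,
                        ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  pool <- .pool_cohorts(datasets)
  if (!protein %in% colnames(pool$analytes)) stop("unknown protein: ", protein)
  qa <- assignQuartiles(pool$analytes[, protein])
  if (is.null(adjust)) adjust <- if (pool$pooled) c("stage", "treatment") else character()
  x <- cbind(q2 = as.numeric(qa$labels == "Q2"),
             q3 = as.numeric(qa$labels == "Q3"),
             q4 = as.numeric(qa$labels == "Q4"))
  if ("stage" %in% adjust) x <- cbind(x, stage3 = as.numeric(pool$patients$stage == "III"))
  if ("treatment" %in% adjust) x <- cbind(x, no_bt = as.numeric(pool$patients$treatment == "EBRT"))
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  if (!all(keep[c("q2", "q3", "q4")])) stop("rank-deficient quartile design")
  fit <- coxFit(pool$patients$time, pool$patients$event, x[, keep, drop = FALSE],
                ties = ties)
  ev_by_q <- tapply(pool$patients$event, qa$labels, sum, default = 0)
  flagged <- names(ev_by_q)[ev_by_q == 0]
  row <- data.frame(protein = protein,
                    cohort = pool$label,
                    n_q1 = qa$counts[["Q1"]], n_q2 = qa$counts[["Q2"]],
                    n_q3 = qa$counts[["Q3"]], n_q4 = qa$counts[["Q4"]],
                    stringsAsFactors = FALSE)
  for (q in c("q2", "q3", "q4")) {
    row[[paste0("hr_", q)]] <- unname(fit$hr[q])
    row[[paste0("ci_lo_", q)]] <- unname(fit$ci_lo[q])
    row[[paste0("ci_hi_", q)]] <- unname(fit$ci_hi[q])
    row[[paste0("p_", q)]] <- unname(fit$p[q])
  }
  row$flagged <- paste(flagged, collapse = ",")
  class(row) <- c("quartileHRRow", "data.frame")
  row
}

#' Quartile screening across a protein panel
#'
#' Emits one row per protein for the pooled dataset (with stage/treatment
#' adjustment) and for each cohort separately (no adjusters: they are
#' constant within a cohort); a single-cohort input yields no pooled row.
#' Proteins with Q4 p < 0.05 in any row are flagged as panel candidates,
#' and Holm-adjusted Q4 p-values are reported alongside the raw ones
#' (adjustment across proteins, within each cohort grouping).
#'
#' @param datasets list of [SASPCohort-class] objects.
#' @param proteins character vector of analytes (may be empty).
#' @param ties tie correction.
#' @return data.frame of `quartileCox` rows with `p_holm_q4` and `candidate`.
#' @export
screenPanel <- function(datasets, proteins, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is(datasets, "SASPCohort")) datasets <- list(datasets)
  if (!length(proteins)) {
    return(data.frame(protein = character(), cohort = character()))
  }
  groups <- lapply(datasets, list)
  names(groups) <- vapply(datasets, cohortLabel, character(1))
  if (length(datasets) > 1) groups <- c(list(all = datasets), groups)
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(proteins, function(pr)
      quartileCox(groups[[g]], pr, ties = ties)))
  }))
  rows$p_holm_q4 <- unlist(lapply(split(rows$p_q4, rows$cohort)[unique(rows$cohort)],
                                  p.adjust, method = "holm"), use.names = FALSE)
  cand <- tapply(rows$p_q4 < 0.05, rows$protein, any)
  rows$candidate <- unname(cand[rows$protein])
  rownames(rows) <- NULL
  rows
}

#' Named protein-panel presets
#'
#' `p8` and `p7` are the two published panels of survival-associated
#' SASP proteins; `p8` = CRP, GRO, LEPTIN, MIG, MMP1, SCCA, SAA, sIL2Ra;
#' `p7` = CRP, GRO, LEPTIN, MIG, MMP1, SCCA, HGF.
#' @param preset `"p8"`, `"p7"`, or a character vector used as-is.
#' @export
saspPanel <- function(preset = c("p8", "p7")) {
  if (length(preset) > 1 && !all(preset %in% c("p8", "p7")))
    return(preset)
  preset <- match.arg(preset)
  switch(preset,
         p8 = c("CRP", "GRO", "LEPTIN", "MIG", "MMP1", "SCCA", "SAA", "sIL2Ra"),
         p7 = c("CRP", "GRO", "LEPTIN", "MIG", "MMP1", "SCCA", "HGF"))
}
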