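#' @include quartiles.R
NULL

# plain-list view of a cohort for hot loops (avoids repeated DataFrame
# coercion); functions below accept either a SASPCohort or this cache
.cohort_cache <- function(x) {
  if (is(x, "SASPCohort"))
    list(pd = patientData(x), am = analyteMatrix(x), label = cohortLabel(x))
  else x
}

# order-statistic percentile: smallest order statistic q with
# #{x <= q} >= ceiling(p * n); for tie-free x exactly ceiling(p * n)
# values fall at or below it
.cutoff_quantile <- function(x, pct) {
  unname(quantile(x, pct / 100, type = 1, names = FALSE))
}

#' Draw event-stratified 50/50 train/test partitions
#'
#' Each pair is a random partition of the cohort into disjoint train/test
#' subsets (sampling without replacement), stratified on the event indicator
#' so both halves contain events. Reproducible from the seed.
#'
#' @param event 0/1 event indicator (defines n and the strata).
#' @param nPairs number of partitions.
#' @param fraction train percentage in (0, 100); default 50.
#' @param seed integer.
#' @return list of `nPairs` lists with integer index vectors `train`, `test`.
#' @export
sampleSplitPairs <- function(event, nPairs, fraction = 50, seed = 1L) {
  n <- length(event)
  if (nPairs < 1) stop("nPairs must be >= 1")
  if (fraction <= 0 || fraction >= 100) stop("fraction must be in (0, 100)")
  if (sum(event) < 2) stop("cohort has fewer than 2 events: cannot stratify")
  ev <- which(event == 1)
  ce <- which(event == 0)
  f <- fraction / 100
  n_ev <- min(max(round(f * length(ev)), 1L), length(ev) - 1L)
  n_ce <- round(f * n) - n_ev
  n_ce <- min(max(n_ce, 0L), length(ce))
  .with_seed(seed, {
    lapply(seq_len(nPairs), function(i) {
      tr <- c(sample(ev, n_ev), sample(ce, n_ce))
      list(train = sort(tr), test = sort(setdiff(seq_len(n), tr)))
    })
  })
}

#' Train one ridge score with a frozen percentile cutoff
#'
#' Fits an L2-penalized Cox model on the training subset (penalty selected by
#' cross-validation on that subset only, unless a numeric `lambda` is given),
#' computes training scores, freezes the dichotomization cutoff at the
#' `cutoffPercentile`-th order-statistic percentile of the training scores,
#' and orients the score so that the above-cutoff group has training hazard
#' ratio >= 1 (coefficients negated if needed; recorded in
#' `orientationFlipped`).
#'
#' @param cohort a [SASPCohort-class].
#' @param proteins analyte panel (see [saspPanel()]).
#' @param trainIdx integer indices of the training subset (default: all).
#' @param cutoffPercentile percent of training patients labeled low
#'   (default 40, the 40th-percentile rule; use 60 for cohorts where the
#'   high-risk stratum is the top 40%).
#' @param lambda `"cv"` or a fixed numeric penalty.
#' @param nFolds,lambdaGrid passed to [cvLambdaMin()] when `lambda = "cv"`.
#' @param seed seed for the CV fold assignment.
#' @param ties tie correction.
#' @param family `"cox"` (default) or `"binomial"` (logistic on the
#'   event-by-horizon indicator).
#' @param modelId integer id stored in the model (the split index).
#' @return a [RidgeCoxModel-class]
#' @export
trainModel <- function(cohort, proteins, trainIdx = NULL,
                       cutoffPercentile = 40, lambda = "cv", nFolds = 10,
                       lambdaGrid = .default_lambda_grid(), seed = 1L,
                       ties = c("efron", "breslow"),
                       family = c("cox", "binomial"), modelId = 0L) {
  ties <- match.arg(ties)
  family <- match.arg(family)
  cc <- .cohort_cache(cohort)
  am <- cc$am
  miss <- setdiff(proteins, colnames(am))
  if (length(miss)) stop("panel proteins absent: ", paste(miss, collapse = ", "))
  pd <- cc$pd
  if (is.null(trainIdx)) trainIdx <- seq_len(nrow(pd))
  x <- am[trainIdx, proteins, drop = FALSE]
  time <- pd$time[trainIdx]
  event <- pd$event[trainIdx]
  if (sum(event) == 0) stop("no events in the training subset")

  cv <- NULL
  if (identical(lambda, "cv")) {
    cv <- cvLambdaMin(x, time, event, nFolds = nFolds,
                      lambdaGrid = lambdaGrid, seed = seed, ties = ties)
    lambda <- cv$lambda
  }
  fit <- if (family == "cox") {
    ridgeCoxFit(x, time, event, lambda = lambda, ties = ties,
                cvCurve = cv$cvCurve)
  } else {
    .ridge_logistic_fit(x, event, lambda = lambda)
  }
  scores <- linearPredictor(fit, x)
  if (diff(range(scores)) < 1e-12)
    stop("degenerate scores: all training patients identical under the model")

  cutoff <- .cutoff_quantile(scores, cutoffPercentile)
  high <- scores > cutoff
  flipped <- FALSE
  if (length(unique(high)) == 2) {
    hr <- tryCatch(
      suppressWarnings(coxFit(time, event, cbind(high = as.numeric(high)),
                              ties = ties)$hr[["high"]]),
      error = function(e) NA_real_)
    if (is.finite(hr) && hr < 1) {
      fit@beta <- -fit@beta
      scores <- -scores
      cutoff <- .cutoff_quantile(scores, cutoffPercentile)
      flipped <- TRUE
    }
  }
  new("RidgeCoxModel", modelId = as.integer(modelId), proteins = proteins,
      fit = fit, cutoffPercentile = cutoffPercentile, cutoffValue = cutoff,
      orientationFlipped = flipped, trainLabel = cc$label)
}

#' Dichotomize patients with a frozen score cutoff
#'
#' Labels a patient `SASP_H` iff their oriented score strictly exceeds the
#' model's frozen training cutoff; a score exactly at the cutoff goes low.
#' The cutoff is never re-derived on new data.
#'
#' @param model a [RidgeCoxModel-class].
#' @param newdata a [SASPCohort-class] or patients x analytes matrix.
#' @return factor with levels `SASP_L`, `SASP_H`, named by patient id when
#'   available.
#' @export
dichotomize <- function(model, newdata) {
  s <- linearPredictor(model, newdata)
  factor(ifelse(s > model@cutoffValue, "SASP_H", "SASP_L"),
         levels = c("SASP_L", "SASP_H"))
}

# two-group Cox of SASP_H vs SASP_L; NA row when a single label is present
.two_group_eval <- function(time, event, labels, ties = "efron") {
  if (length(unique(labels)) < 2 || sum(event) == 0) {
    return(list(hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                p = NA_real_, p_logrank = NA_real_, n = length(time),
                flagged = TRUE))
  }
  x <- cbind(high = as.numeric(labels == "SASP_H"))
  fit <- suppressWarnings(coxFit(time, event, x, ties = ties))
  lr <- logrankTest(time, event, labels)
  list(hr = unname(fit$hr["high"]), ci_lo = unname(fit$ci_lo["high"]),
       ci_hi = unname(fit$ci_hi["high"]), p = unname(fit$p["high"]),
       p_logrank = lr$p, n = length(time), flagged = !fit$converged)
}

#' Evaluate a model on its train/test halves
#'
#' Unadjusted two-group Cox hazard ratio (SASP_H vs SASP_L), 95% CI and
#' two-sided Wald p (log-rank p alongside) on each half, using the frozen
#' training cutoff on the test half. A half left with a single label is
#' flagged with undefined HR.
#'
#' @param model a [RidgeCoxModel-class].
#' @param cohort the cohort the split indices refer to.
#' @param trainIdx,testIdx disjoint index vectors.
#' @param ties tie correction.
#' @return list with elements `train` and `test`.
#' @export
evaluateSplit <- function(model, cohort, trainIdx, testIdx,
                          ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(intersect(trainIdx, testIdx)))
    stop("train and test indices overlap")
  cc <- .cohort_cache(cohort)
  pd <- cc$pd
  am <- cc$am
  ev <- lapply(list(train = trainIdx, test = testIdx), function(idx) {
    labels <- dichotomize(model, am[idx, , drop = FALSE])
    .two_group_eval(pd$time[idx], pd$event[idx], labels, ties = ties)
  })
  ev
}

#' Run the split-pair ridge ensemble on one cohort
#'
#' For each of `nPairs` event-stratified 50/50 partitions: train a ridge
#' score on the training half ([trainModel()]), evaluate the dichotomized
#' groups on both halves ([evaluateSplit()]), and collect a
#' [ModelRecord-class]. Splits where training fails (degenerate scores,
#' no events) are skipped. The model id is the split index.
#'
#' @param cohort a [SASPCohort-class].
#' @param proteins analyte panel.
#' @param nPairs number of train/test pairs (3000 at full scale).
#' @param cutoffPercentile,lambda,nFolds,lambdaGrid,ties,family see
#'   [trainModel()].
#' @param seed master seed; split sampling and per-split CV seeds derive
#'   from it deterministically.
#' @return list of [ModelRecord-class] objects.
#' @export
runEnsemble <- function(cohort, proteins, nPairs, cutoffPercentile = 40,
                        lambda = "cv", nFolds = 10,
                        lambdaGrid = .default_lambda_grid(), seed = 1L,
                        ties = c("efron", "breslow"),
                        family = c("cox", "binomial")) {
  ties <- match.arg(ties)
  family <- match.arg(family)
  cohort <- .cohort_cache(cohort)
  pd <- cohort$pd
  pairs <- sampleSplitPairs(pd$event, nPairs, fraction = 50, seed = seed)
  records <- vector("list", nPairs)
  for (i in seq_len(nPairs)) {
    rec <- tryCatch({
      m <- trainModel(cohort, proteins, trainIdx = pairs[[i]]$train,
                      cutoffPercentile = cutoffPercentile, lambda = lambda,
                      nFolds = nFolds, lambdaGrid = lambdaGrid,
                      seed = .derive_seed(seed, i), ties = ties,
                      family = family, modelId = i)
      se <- evaluateSplit(m, cohort, pairs[[i]]$train, pairs[[i]]$test,
                          ties = ties)
      new("ModelRecord", model = m, splitEval = se, bootstrap = list(),
          external = data.frame())
    }, error = function(e) NULL)
    records[[i]] <- rec
  }
  Filter(Negate(is.null), records)
}

# deterministic per-stage/per-split seed derivation (kept below 2^31)
.derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483647)
}

#' Select models consistent across the split halves
#'
#' Keeps models whose train AND test hazard ratios are at least `hrMin` with
#' both Wald p-values at most `pMax` (defaults 3.0 / 0.05, matching the
#' published model tables where every listed train/test HR exceeds 3 at
#' p < 0.05). Records are sorted by bootstrap performance when available
#' (fewest non-significant bootstraps, then mean HR), otherwise by test p.
#'
#' @param records list of [ModelRecord-class].
#' @param hrMin,pMax selection gates.
#' @param maxModels cap on the number of selected models (default unlimited).
#' @return list of selected [ModelRecord-class] (possibly empty).
#' @export
selectModels <- function(records, hrMin = 3.0, pMax = 0.05, maxModels = Inf) {
  if (!length(records)) stop("no records supplied")
  keep <- Filter(function(r) {
    se <- r@splitEval
    all(is.finite(c(se$train$hr, se$test$hr, se$train$p, se$test$p))) &&
      se$train$hr >= hrMin && se$test$hr >= hrMin &&
      se$train$p <= pMax && se$test$p <= pMax
  }, records)
  if (!length(keep)) return(keep)
  key <- vapply(keep, function(r) {
    if (length(r@bootstrap)) r@bootstrap$bins[["p_gt_0.05"]] * 1e6 - r@bootstrap$mean_hr
    else r@splitEval$test$p
  }, numeric(1))
  keep <- keep[order(key)]
  head(keep, if (is.finite(maxModels)) maxModels else length(keep))
}

#' Subsample bootstrap validation of one model
#'
#' Each of `nBoot` iterations draws `subsampleFraction` percent of the
#' cohort without replacement (classical with-replacement resampling via
#' `replace = TRUE`), recomputes scores with the frozen coefficients,
#' re-derives the cutoff at the model's percentile *within the subsample*,
#' and fits the two-group Cox model. Iterations whose subsample lacks events
#' or yields a single label are redrawn (up to 10 attempts each, then
#' counted as non-significant). Reported are the mean hazard ratio
#' (arithmetic, or geometric via `meanType`), the three p-value bins
#' (p > 0.05, 0.001 < p <= 0.05, p <= 0.001) and the pass flag
#' (at least 95% of iterations with p < 0.05).
#'
#' @param model a [RidgeCoxModel-class].
#' @param cohort the cohort to resample (typically the training cohort).
#' @param nBoot iterations (1000 at full scale).
#' @param subsampleFraction percent of patients per subsample (default 70).
#' @param seed integer.
#' @param replace draw with replacement instead (default FALSE).
#' @param meanType `"arithmetic"` or `"geometric"`.
#' @param ties tie correction.
#' @return list: `n_boot`, `subsample_fraction`, `mean_hr`, `bins` (named
#'   numeric, summing to `n_boot`), `pass`, `n_redrawn`.
#' @export
bootstrapValidate <- function(model, cohort, nBoot = 1000,
                              subsampleFraction = 70, seed = 1L,
                              replace = FALSE,
                              meanType = c("arithmetic", "geometric"),
                              ties = c("efron", "breslow")) {
  meanType <- match.arg(meanType)
  ties <- match.arg(ties)
  cc <- .cohort_cache(cohort)
  pd <- cc$pd
  scores <- linearPredictor(model@fit, cc$am)
  n <- nrow(pd)
  m <- max(2L, floor(subsampleFraction / 100 * n))
  .with_seed(seed, {
    hrs <- ps <- rep(NA_real_, nBoot)
    n_redrawn <- 0L
    for (b in seq_len(nBoot)) {
      for (attempt in 1:10) {
        idx <- sample(n, m, replace = replace)
        s <- scores[idx]
        cut_b <- .cutoff_quantile(s, model@cutoffPercentile)
        lab <- ifelse(s > cut_b, "SASP_H", "SASP_L")
        ok <- sum(pd$event[idx]) > 0 && length(unique(lab)) == 2
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      if (!ok) next
      fit <- tryCatch(
        suppressWarnings(coxFit(pd$time[idx], pd$event[idx],
                                cbind(high = as.numeric(lab == "SASP_H")),
                                ties = ties)),
        error = function(e) NULL)
      if (is.null(fit)) next
      hrs[b] <- unname(fit$hr["high"])
      ps[b] <- unname(fit$p["high"])
    }
    bins <- c(p_gt_0.05 = sum(is.na(ps) | ps > 0.05),
              p_0.001_0.05 = sum(!is.na(ps) & ps <= 0.05 & ps > 0.001),
              p_le_0.001 = sum(!is.na(ps) & ps <= 0.001))
    mean_hr <- if (meanType == "arithmetic") mean(hrs, na.rm = TRUE)
               else exp(mean(log(hrs), na.rm = TRUE))
    list(n_boot = nBoot, subsample_fraction = subsampleFraction,
         mean_hr = mean_hr, bins = bins,
         pass = bins[["p_gt_0.05"]] <= 0.05 * nBoot, n_redrawn = n_redrawn)
  })
}

#' Cross-cohort validation with the frozen cutoff
#'
#' Applies the model's frozen coefficients and cutoff to each independent
#' cohort and fits the two-group Cox model. Validating on the training
#' cohort is refused; a degenerate label distribution is flagged.
#'
#' @param model a [RidgeCoxModel-class].
#' @param cohorts list of [SASPCohort-class] excluding the training cohort.
#' @param ties tie correction.
#' @return data.frame with one row per cohort: `cohort`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `p_logrank`, `n`, `flagged`.
#' @export
externalValidate <- function(model, cohorts, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is(cohorts, "SASPCohort")) cohorts <- list(cohorts)
  labs <- vapply(cohorts, cohortLabel, character(1))
  if (model@trainLabel %in% labs)
    stop("validation cohorts must exclude the training cohort (", model@trainLabel, ")")
  do.call(rbind, lapply(cohorts, function(co) {
    pd <- patientData(co)
    ev <- .two_group_eval(pd$time, pd$event, dichotomize(model, co), ties = ties)
    data.frame(cohort = cohortLabel(co), hr = ev$hr, ci_lo = ev$ci_lo,
               ci_hi = ev$ci_hi, p = ev$p, p_logrank = ev$p_logrank,
               n = ev$n, flagged = ev$flagged, stringsAsFactors = FALSE)
  }))
}
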