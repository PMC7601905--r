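#' @include preprocess.R
NULL

.as_cov_matrix <- function(covariates) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

#' Kaplan-Meier product-limit estimate
#'
#' Ties are handled by simultaneous drops; at equal times events precede
#' censorings. The survival probability drops only at event times.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return data.frame of class `kmCurve` with columns `time`, `at_risk`,
#'   `events`, `censored`, `survival`, one row per distinct observed time.
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("empty input")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  sf <- survfit(Surv(time, event) ~ 1, conf.type = "none")
  structure(data.frame(time = sf$time, at_risk = sf$n.risk,
                       events = sf$n.event, censored = sf$n.censor,
                       survival = sf$surv),
            class = c("kmCurve", "data.frame"))
}

#' Step-function evaluation of a Kaplan-Meier curve
#' @param curve a `kmCurve` from [kmEstimate()]
#' @param at times at which to evaluate S(t); S(t) = 1 before the first
#'   observed time
#' @export
kmSurvivalAt <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic. If the two groups
#' combined contain no events the statistic is 0 with p = 1.
#'
#' @param time,event pooled follow-up data.
#' @param group two-level grouping vector.
#' @return list with `chi2` and `p`.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stop("exactly two non-empty groups required")
  if (sum(event) == 0) return(list(chi2 = 0, p = 1))
  sd <- survdiff(Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Partial-likelihood maximization via [survival::coxph()] with the Efron
#' tie correction by default (Breslow available). Monotone likelihood
#' (perfect separation of events) is flagged: the fit is marked
#' non-converged and diverging coefficients are capped at +/- 15 on the log
#' scale.
#'
#' @param time,event follow-up data (at least one event).
#' @param covariates matrix or data.frame of numeric covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `coxFitSummary`: `beta`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`, `p` (two-sided Wald), `loglik`, `converged`.
#' @export
coxFit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- .as_cov_matrix(covariates)
  if (sum(event) == 0) stop("no events: Cox model undefined")
  diverged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, ties = ties,
          control = coxph.control(eps = 1e-12, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta", conditionMessage(w), ignore.case = TRUE))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  # a contrast-free (constant) covariate carries no information: beta 0, HR 1
  no_contrast <- is.na(beta)
  beta[no_contrast] <- 0
  se[no_contrast] <- Inf
  converged <- !diverged && all(is.finite(beta)) && all(abs(beta) <= 15)
  beta <- pmin(pmax(beta, -15), 15)
  if (!converged)
    warning("monotone likelihood or non-convergence: coefficients capped, fit flagged")
  names(beta) <- colnames(x)
  z <- beta / se
  structure(list(beta = beta, se = setNames(se, colnames(x)),
                 hr = exp(beta),
                 ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
                 p = 2 * pnorm(-abs(z)),
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = converged, ties = ties, n = length(time),
                 n_event = sum(event)),
            class = "coxFitSummary")
}

.standardize <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl)
}

#' L2-penalized Cox (ridge) fit
#'
#' Maximizes `logPL(beta) - lambda/2 * ||beta||^2` by Newton-Raphson on
#' covariates standardized to zero mean and unit variance (the
#' transformation is frozen in the returned object and reapplied verbatim by
#' [linearPredictor()]). `lambda = 0` reduces to the unpenalized fit.
#' Convergence at max |score| < 1e-8 or 50 iterations.
#'
#' @param covariates patients x covariates matrix.
#' @param time,event follow-up data (at least one event).
#' @param lambda penalty weight >= 0.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param standardize center/scale covariates before penalization (default
#'   TRUE; penalty fairness across analytes with different scales).
#' @param cvCurve optional CV curve to store (set by [cvLambdaMin()] users).
#' @return a [RidgeCoxFit-class]
#' @export
ridgeCoxFit <- function(covariates, time, event, lambda,
                        ties = c("efron", "breslow"), standardize = TRUE,
                        cvCurve = NULL) {
  ties <- match.arg(ties)
  if (lambda < 0) stop("lambda must be >= 0")
  if (sum(event) == 0) stop("no events: Cox model undefined")
  x <- .as_cov_matrix(covariates)
  std <- if (standardize) .standardize(x) else
    list(x = x, center = setNames(rep(0, ncol(x)), colnames(x)),
         scale = setNames(rep(1, ncol(x)), colnames(x)))
  ord <- order(time)
  sol <- .ridge_cox_solve(std$x[ord, , drop = FALSE], time[ord], event[ord],
                          lambda, rep(0, ncol(x)), ties == "efron", 1e-8, 50L)
  beta <- pmin(pmax(drop(sol$beta), -50), 50)
  new("RidgeCoxFit", beta = setNames(beta, colnames(x)), lambda = lambda,
      center = setNames(std$center, colnames(x)),
      scale = setNames(std$scale, colnames(x)),
      loglik = sol$loglik, converged = isTRUE(sol$converged),
      ties = ties, family = "cox", cvCurve = cvCurve)
}

#' Unpenalized partial log-likelihood of a coefficient vector
#' @noRd
.partial_loglik <- function(x, time, event, beta, ties) {
  ord <- order(time)
  .cox_partial_loglik(x[ord, , drop = FALSE], time[ord], event[ord],
                      beta, ties == "efron")
}

.default_lambda_grid <- function() exp(seq(log(1e3), log(1e-3), length.out = 50))

.stratified_folds <- function(event, nFolds) {
  fold <- integer(length(event))
  for (g in list(which(event == 1), which(event == 0))) {
    if (length(g))
      fold[g] <- sample(rep_len(seq_len(nFolds), length(g)))
  }
  fold
}

#' Cross-validated ridge penalty selection
#'
#' Event-stratified k-fold cross-validation over a penalty grid, scoring each
#' penalty by the Verweij-van Houwelingen partial-likelihood deviance
#' `-2 * (logPL_full(beta_-k) - logPL_-k(beta_-k))` summed over folds.
#' Returns the grid value minimizing the CV deviance (the largest such value
#' on ties, favoring shrinkage). If a fold assignment leaves a training set
#' without events it is redrawn (up to 10 attempts).
#'
#' @param covariates,time,event as in [ridgeCoxFit()].
#' @param nFolds number of folds (>= 3, default 10).
#' @param lambdaGrid penalty grid; default 50 values log-spaced over
#'   `[1e-3, 1e3]`.
#' @param seed integer; fold assignment is deterministic given the seed.
#' @param ties tie correction.
#' @return list with `lambda` (the selected penalty) and `cvCurve`
#'   (data.frame `lambda`, `cv_deviance`).
#' @export
cvLambdaMin <- function(covariates, time, event, nFolds = 10,
                        lambdaGrid = .default_lambda_grid(), seed = 1L,
                        ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (nFolds < 3) stop("nFolds must be >= 3")
  if (!length(lambdaGrid)) stop("empty lambda grid")
  x <- .as_cov_matrix(covariates)
  std <- .standardize(x)
  lambdas <- sort(lambdaGrid, decreasing = TRUE)  # warm starts from heavy shrinkage
  efron <- ties == "efron"

  folds <- .with_seed(seed, {
    for (attempt in 1:10) {
      f <- .stratified_folds(event, nFolds)
      ok <- all(vapply(seq_len(nFolds), function(k) sum(event[f != k]) > 0, logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not build folds with events in every training set")
    f
  })

  ord_all <- order(time)
  dev <- .ridge_cox_cv_dev(std$x[ord_all, , drop = FALSE], time[ord_all],
                           event[ord_all], folds[ord_all], nFolds, lambdas,
                           efron, 1e-8, 50L)
  mean_dev <- colMeans(dev)
  best <- which(mean_dev <= min(mean_dev) + 1e-12)[1]  # largest lambda on ties
  list(lambda = lambdas[best],
       cvCurve = data.frame(lambda = lambdas, cv_deviance = mean_dev))
}

#' L2-penalized logistic fit for the event-by-horizon outcome
#'
#' Companion to [ridgeCoxFit()] behind the `family` switch of
#' [trainModel()]: penalized IRLS for `P(event by horizon)` with the same
#' frozen standardization contract.
#' @noRd
.ridge_logistic_fit <- function(covariates, y, lambda, maxit = 100) {
  x <- .as_cov_matrix(covariates)
  std <- .standardize(x)
  xs <- cbind(`(Intercept)` = 1, std$x)
  beta <- rep(0, ncol(xs))
  pen <- c(0, rep(lambda, ncol(xs) - 1))  # intercept unpenalized
  for (i in seq_len(maxit)) {
    eta <- drop(xs %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(xs, y - mu)) - pen * beta
    hess <- crossprod(xs * w, xs) + diag(pen, ncol(xs))
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(grad)) < 1e-8) break
  }
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  new("RidgeCoxFit", beta = setNames(beta[-1], colnames(x)), lambda = lambda,
      center = setNames(std$center, colnames(x)),
      scale = setNames(std$scale, colnames(x)),
      loglik = ll, converged = max(abs(grad)) < 1e-6,
      ties = "efron", family = "binomial", cvCurve = NULL)
}

#' @rdname linearPredictor
#' @export
setMethod("linearPredictor", signature(fit = "RidgeCoxFit"),
  function(fit, newdata) {
    x <- if (is(newdata, "SASPCohort")) analyteMatrix(newdata) else as.matrix(newdata)
    miss <- setdiff(names(fit@beta), colnames(x))
    if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
    x <- x[, names(fit@beta), drop = FALSE]
    xs <- sweep(sweep(x, 2, fit@center), 2, fit@scale, "/")
    drop(xs %*% fit@beta)
  })

#' @rdname linearPredictor
#' @export
setMethod("linearPredictor", signature(fit = "RidgeCoxModel"),
  function(fit, newdata) linearPredictor(fit@fit, newdata))
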