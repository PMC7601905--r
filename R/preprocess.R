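#' @include simulate.R
NULL

#' Quality-control filter for multiplex bead-array wells
#'
#' Flags wells with too few beads (`low_beads`) and replicate groups whose
#' coefficient of variation of MFI exceeds `maxCvPct` (`high_cv`). Each
#' excluded well carries exactly one primary reason: a low-bead well is never
#' additionally flagged for CV, and replicate CVs are computed over the wells
#' that survive the bead filter (so the filter is idempotent). CV uses the
#' sample (n-1) standard deviation: `CV = sd/mean * 100`. Groups with fewer
#' than two bead-passing wells cannot be assessed and pass.
#'
#' @param wells data.frame with columns `well`, `mfi`, `bead_count`,
#'   `replicate` (replicate-group id).
#' @param minBeads minimum bead count per well (default 35).
#' @param maxCvPct maximum replicate CV in percent (default 25).
#' @return list with `flagged` (data.frame `well`, `reason`, `cv_pct`),
#'   `cv` (data.frame `replicate`, `cv_pct`), and `keep` (ids of passing
#'   wells).
#' @export
qcFilter <- function(wells, minBeads = 35, maxCvPct = 25) {
  if (!nrow(wells)) stop("no wells supplied")
  if (minBeads < 0 || maxCvPct < 0) stop("thresholds must be non-negative")
  low <- wells$bead_count < minBeads
  ok <- wells[!low, , drop = FALSE]
  cvs <- if (nrow(ok)) {
    vapply(split(ok$mfi, ok$replicate), function(x) {
      if (length(x) < 2) NA_real_ else sd(x) / mean(x) * 100
    }, numeric(1))
  } else setNames(numeric(0), character(0))
  cv_df <- data.frame(replicate = names(cvs), cv_pct = unname(cvs),
                      stringsAsFactors = FALSE)
  bad_grp <- names(cvs)[!is.na(cvs) & cvs > maxCvPct]
  high <- !low & wells$replicate %in% bad_grp
  flagged <- rbind(
    data.frame(well = wells$well[low],
               reason = rep("low_beads", sum(low)),
               cv_pct = rep(NA_real_, sum(low)), stringsAsFactors = FALSE),
    data.frame(well = wells$well[high],
               reason = rep("high_cv", sum(high)),
               cv_pct = unname(cvs[wells$replicate[high]]),
               stringsAsFactors = FALSE))
  list(flagged = flagged, cv = cv_df, keep = wells$well[!low & !high])
}

#' Fit a log2-log2 standard curve
#'
#' Least-squares fit of `log2(MFI)` on `log2(concentration)` over the
#' standard wells (linear by default, optionally quadratic). The fitted
#' curve must be monotone increasing over the range of the standards; a
#' non-monotone fit is returned with `monotone = FALSE` and a warning, and
#' is refused by [estimateConcentration()].
#'
#' @param standards data.frame of standard wells with columns `mfi` and
#'   `known_conc` (and optionally `analyte`).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return object of class `standardCurve`: coefficients in log2-log2 space,
#'   the log2 MFI and concentration fit ranges, residual summary, and the
#'   monotonicity flag.
#' @export
fitStandardCurve <- function(standards, degree = 1) {
  stopifnot(degree %in% c(1, 2))
  conc <- standards$known_conc
  if (length(unique(conc)) < 4)
    stop("need at least 4 standards with distinct concentrations")
  x <- log2(conc)
  y <- log2(standards$mfi)
  fit <- if (degree == 1) lm(y ~ x) else lm(y ~ x + I(x^2))
  cf <- unname(coef(fit))
  if (degree == 1) cf <- c(cf, 0)
  xr <- range(x)
  # derivative b1 + 2*b2*x is linear in x: check the endpoints
  mono <- all(cf[2] + 2 * cf[3] * xr > 0)
  if (!mono) warning("fitted standard curve is not monotone increasing; curve rejected")
  structure(list(
    analyte = if ("analyte" %in% names(standards)) standards$analyte[1] else NA_character_,
    coef = c(intercept = cf[1], slope = cf[2], quad = cf[3]),
    degree = degree,
    fitRangeMfi = range(y), fitRangeConc = xr,
    residual_sd = sd(residuals(fit)), monotone = mono),
    class = "standardCurve")
}

#' Estimate log2 concentration from MFI via an inverted standard curve
#'
#' Inverts the calibration function at `log2(mfi)`. Values outside the MFI
#' range spanned by the standards are extrapolated but flagged
#' `out_of_range`.
#'
#' @param mfi numeric vector of median fluorescence intensities (> 0).
#' @param curve a `standardCurve` from [fitStandardCurve()].
#' @return data.frame with columns `log2_conc` and `out_of_range`.
#' @export
estimateConcentration <- function(mfi, curve) {
  stopifnot(inherits(curve, "standardCurve"))
  if (!curve$monotone) stop("cannot estimate from a rejected (non-monotone) curve")
  if (any(mfi <= 0)) stop("mfi must be > 0")
  y <- log2(mfi)
  b <- curve$coef
  x <- if (curve$degree == 1 || abs(b["quad"]) < 1e-12) {
    (y - b["intercept"]) / b["slope"]
  } else {
    # roots of quad*x^2 + slope*x + (intercept - y); keep the branch where
    # the curve is increasing (positive derivative)
    disc <- pmax(b["slope"]^2 - 4 * b["quad"] * (b["intercept"] - y), 0)
    r1 <- (-b["slope"] + sqrt(disc)) / (2 * b["quad"])
    r2 <- (-b["slope"] - sqrt(disc)) / (2 * b["quad"])
    ifelse(b["slope"] + 2 * b["quad"] * r1 > 0, r1, r2)
  }
  data.frame(log2_conc = unname(x),
             out_of_range = y < curve$fitRangeMfi[1] | y > curve$fitRangeMfi[2])
}

#' Apply administrative censoring at a fixed horizon
#'
#' Follow-up beyond the horizon is truncated to the horizon with the event
#' indicator cleared; a time exactly equal to the horizon keeps its event
#' status (censoring applies to times strictly greater than the horizon).
#' Deaths from unrelated causes are expected to be encoded upstream as
#' `event = 0` at the death time.
#'
#' @param time positive follow-up times in years.
#' @param event 0/1 event indicators.
#' @param horizon censoring horizon in years (default 5).
#' @return data.frame with censored `time` and `event`.
#' @export
censorAtHorizon <- function(time, event, horizon = 5) {
  if (horizon <= 0) stop("horizon must be > 0")
  if (any(time <= 0)) stop("all times must be > 0")
  stopifnot(all(event %in% c(0, 1)), length(time) == length(event))
  over <- time > horizon
  data.frame(time = ifelse(over, horizon, time),
             event = as.integer(ifelse(over, 0L, event)))
}

#' Quantify a plate into a patients-by-analytes log2 matrix
#'
#' Convenience wrapper for the full preprocessing path: QC filter, per-analyte
#' standard-curve fit on the passing standard wells, concentration estimation
#' for the passing sample wells, and replicate averaging on the log2 scale.
#'
#' @param plate data.frame as produced by [simulatePlate()].
#' @param minBeads,maxCvPct QC thresholds, see [qcFilter()].
#' @param degree standard-curve degree, see [fitStandardCurve()].
#' @return list with `log2` (replicate-averaged log2 concentrations, one row
#'   per sample replicate group), `qc` (the QC report) and `curves`.
#' @export
quantifyPlate <- function(plate, minBeads = 35, maxCvPct = 25, degree = 1) {
  qc <- qcFilter(plate, minBeads = minBeads, maxCvPct = maxCvPct)
  kept <- plate[plate$well %in% qc$keep, , drop = FALSE]
  out <- lapply(split(kept, kept$analyte), function(d) {
    curve <- fitStandardCurve(d[d$is_standard, , drop = FALSE], degree = degree)
    samp <- d[!d$is_standard, , drop = FALSE]
    est <- estimateConcentration(samp$mfi, curve)
    agg <- tapply(est$log2_conc, samp$replicate, mean)
    list(curve = curve,
         log2 = data.frame(replicate = names(agg), analyte = d$analyte[1],
                           log2_conc = unname(agg), stringsAsFactors = FALSE))
  })
  list(log2 = do.call(rbind, c(lapply(out, `[[`, "log2"), make.row.names = FALSE)),
       qc = qc,
       curves = lapply(out, `[[`, "curve"))
}
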