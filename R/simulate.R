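#' @include AllGenerics.R
NULL

.ANALYTES <- c("CRP", "GRO", "HGF", "IGFBP2", "LEPTIN", "MIG", "MMP1",
               "PDGFAA", "PDGFAA.AB", "SAA", "SCCA", "sE.Selectin", "sEGFR",
               "sIL1RII", "sIL2Ra", "sIL6R", "sTNFRI", "sTNFRII", "tPAI1")

# the ten analytes tied to the latent senescence factor; leptin loads
# negatively (higher leptin, better survival), the other nine positively
.SASP_POSITIVE <- c("CRP", "GRO", "HGF", "MIG", "MMP1", "SAA", "SCCA",
                    "sIL2Ra", "tPAI1")

.default_loadings <- function(analytes) {
  a <- setNames(numeric(length(analytes)), analytes)
  a[intersect(.SASP_POSITIVE, analytes)] <- 0.8
  if ("LEPTIN" %in% analytes) a["LEPTIN"] <- -0.5
  a
}

#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not
#' perturb the global stream.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation settings for synthetic serum-protein cohorts
#'
#' Defines the generative model the downstream analysis assumes: a single
#' latent senescence factor `z ~ N(0,1)` per patient that (i) shifts a subset
#' of the 19 log2 analyte concentrations through per-analyte loadings and
#' (ii) multiplies the hazard. Event times are exponential given covariates
#' (constant baseline hazard) with linear predictor
#' `logHrStage3 * [stage III] + logHrSenescence * z + noBT(z) * [no BT]`,
#' where the no-brachytherapy log hazard ratio interpolates from
#' `logHrNoBtLow` (at z = -Inf) to `logHrNoBtHigh` (at z = +Inf) through a
#' logistic curve centered at `interactionCenter` with slope
#' `interactionSlope` - so the harm of omitting brachytherapy is concentrated
#' in high-senescence patients. Follow-up is cut by independent exponential
#' loss to follow-up (`dropoutRate`) and administrative censoring at
#' `horizon` years.
#'
#' Defaults mirror the three study cohorts (stage II + brachytherapy n=276;
#' stage III + brachytherapy n=203; stage III without brachytherapy n=86),
#' a stage hazard ratio of 2.3, a no-brachytherapy hazard ratio of 3.3 among
#' high-senescence patients (1.0 among low), a senescence hazard ratio of 1.9
#' per latent-factor unit, and 5-year administrative censoring.
#'
#' @param groupSizes named integer vector of cohort sizes.
#' @param analyteNames analyte identifiers (19 by default).
#' @param analyteMeans,analyteSds per-analyte log2 location/scale, recycled.
#' @param saspLoadings per-analyte loading of the latent factor.
#' @param baselineHazard events per year for the reference patient.
#' @param logHrStage3 natural-log hazard ratio, stage III vs II.
#' @param logHrNoBtHigh,logHrNoBtLow log hazard ratio of omitting
#'   brachytherapy at latent factor +Inf / -Inf.
#' @param logHrSenescence log hazard ratio per unit latent factor.
#' @param interactionCenter,interactionSlope location/steepness of the
#'   logistic interpolation of the no-BT effect in z. The default center,
#'   `qnorm(0.6)`, places the transition at the boundary of the top-40%
#'   latent stratum.
#' @param dropoutRate exponential loss-to-follow-up rate per year.
#' @param horizon administrative censoring time in years.
#' @param ageMean,ageSd age distribution (no hazard effect).
#' @param seed default seed used by [simulateCohorts()].
#' @return an object of class `SASPSimConfig` (a validated list).
#' @examples
#' cfg <- simConfig(groupSizes = c(RTBT2 = 60, RTBT3 = 40, RT3 = 20))
#' cohorts <- simulateCohorts(cfg, seed = 1)
#' @export
simConfig <- function(groupSizes = c(RTBT2 = 276L, RTBT3 = 203L, RT3 = 86L),
                      analyteNames = .ANALYTES,
                      analyteMeans = 10,
                      analyteSds = 1,
                      saspLoadings = .default_loadings(analyteNames),
                      baselineHazard = 0.12,
                      logHrStage3 = log(2.3),
                      logHrNoBtHigh = log(3.3),
                      logHrNoBtLow = log(1.0),
                      logHrSenescence = log(1.9),
                      interactionCenter = qnorm(0.6),
                      interactionSlope = 2,
                      dropoutRate = 0.02,
                      horizon = 5,
                      ageMean = 49, ageSd = 10,
                      seed = 1L) {
  if (is.null(names(groupSizes)) || !all(names(groupSizes) %in% .COHORT_LABELS))
    stop("groupSizes must be named with labels among ", paste(.COHORT_LABELS, collapse = ", "))
  if (any(groupSizes <= 0)) stop("all group sizes must be > 0")
  p <- length(analyteNames)
  analyteMeans <- rep_len(analyteMeans, p)
  analyteSds <- rep_len(analyteSds, p)
  if (any(analyteSds <= 0)) stop("analyteSds must be > 0")
  if (length(saspLoadings) != p)
    stop("saspLoadings must have one entry per analyte (", p, ")")
  if (baselineHazard <= 0) stop("baselineHazard must be > 0")
  if (horizon <= 0) stop("horizon must be > 0")
  if (dropoutRate < 0) stop("dropoutRate must be >= 0")
  cfg <- list(groupSizes = groupSizes, analyteNames = analyteNames,
              analyteMeans = setNames(analyteMeans, analyteNames),
              analyteSds = setNames(analyteSds, analyteNames),
              saspLoadings = setNames(as.numeric(saspLoadings), analyteNames),
              baselineHazard = baselineHazard, logHrStage3 = logHrStage3,
              logHrNoBtHigh = logHrNoBtHigh, logHrNoBtLow = logHrNoBtLow,
              logHrSenescence = logHrSenescence,
              interactionCenter = interactionCenter,
              interactionSlope = interactionSlope,
              dropoutRate = dropoutRate, horizon = horizon,
              ageMean = ageMean, ageSd = ageSd, seed = as.integer(seed))
  class(cfg) <- "SASPSimConfig"
  cfg
}

#' Null simulation settings (no analyte-survival association)
#'
#' All loadings and the latent hazard effect are zero, so the analyte matrix
#' is statistically independent of survival - a negative control for the
#' ensemble's false-selection behavior.
#' @param ... passed to [simConfig()]
#' @export
simConfigNull <- function(...) {
  cfg <- simConfig(...)
  cfg$saspLoadings[] <- 0
  cfg$logHrSenescence <- 0
  cfg
}

#' Expected latent-factor gap between high and low strata
#'
#' For standard-normal z split at the `lowFraction` quantile, the difference
#' `E[z | high] - E[z | low]` via the truncated-normal mean. Used to translate
#' a target high/low-group hazard ratio into a per-unit-z coefficient.
#' @param lowFraction fraction of patients in the low stratum.
#' @export
latentHighLowDelta <- function(lowFraction = 0.4) {
  q <- qnorm(lowFraction)
  dnorm(q) * (1 / (1 - lowFraction) + 1 / lowFraction)
}

#' Simulation settings targeting a given high/low-group hazard ratio
#'
#' Chooses `logHrSenescence` so that the population hazard ratio between the
#' top `1 - lowFraction` and bottom `lowFraction` of the latent factor equals
#' `hrHighLow`.
#' @param hrHighLow target hazard ratio between latent strata.
#' @param lowFraction fraction in the low stratum (matching the cutoff rule).
#' @param ... passed to [simConfig()]
#' @export
simConfigSignal <- function(hrHighLow = 3.5, lowFraction = 0.4, ...) {
  simConfig(logHrSenescence = log(hrHighLow) / latentHighLowDelta(lowFraction), ...)
}

.group_stage <- function(label) if (label == "RTBT2") "II" else "III"
.group_treatment <- function(label) if (label == "RT3") "EBRT" else "EBRT+BT"

.nobt_loghr <- function(cfg, z) {
  cfg$logHrNoBtLow + (cfg$logHrNoBtHigh - cfg$logHrNoBtLow) *
    plogis(cfg$interactionSlope * (z - cfg$interactionCenter))
}

#' Generate synthetic cohorts
#'
#' Draws one [SASPCohort-class] per configured group under the generative
#' model described in [simConfig()]. Fully reproducible from the seed; the
#' latent factor is retained in `colData` as `latent_z` but is never used by
#' the inference code.
#'
#' @param config a `SASPSimConfig`.
#' @param seed integer; defaults to `config$seed`.
#' @return named list of [SASPCohort-class] objects.
#' @export
simulateCohorts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SASPSimConfig"))
  .with_seed(seed, {
    out <- lapply(names(config$groupSizes), function(label) {
      n <- as.integer(config$groupSizes[[label]])
      p <- length(config$analyteNames)
      z <- rnorm(n)
      noise <- matrix(rnorm(n * p), n, p) *
        matrix(config$analyteSds, n, p, byrow = TRUE)
      analytes <- matrix(config$analyteMeans, n, p, byrow = TRUE) +
        outer(z, config$saspLoadings) + noise
      colnames(analytes) <- config$analyteNames

      stage <- .group_stage(label)
      treatment <- .group_treatment(label)
      lp <- config$logHrSenescence * z +
        (stage == "III") * config$logHrStage3 +
        (treatment == "EBRT") * .nobt_loghr(config, z)
      event_time <- rexp(n) / (config$baselineHazard * exp(lp))
      dropout <- if (config$dropoutRate > 0) rexp(n) / config$dropoutRate else rep(Inf, n)
      cens_time <- pmin(dropout, config$horizon)
      time <- pmin(event_time, cens_time)
      event <- as.integer(event_time <= cens_time)

      ids <- sprintf("%s_%04d", label, seq_len(n))
      rownames(analytes) <- ids
      patients <- data.frame(
        id = ids,
        age = round(rnorm(n, config$ageMean, config$ageSd), 1),
        stage = stage, treatment = treatment,
        time = time, event = event, latent_z = z,
        stringsAsFactors = FALSE)
      SASPCohort(patients, analytes, label)
    })
    names(out) <- names(config$groupSizes)
    out
  })
}

#' Construct a SASPCohort from patient records and an analyte matrix
#'
#' @param patients data.frame with columns `id`, `stage`, `treatment`,
#'   `time`, `event` (optionally `age`, `latent_z`).
#' @param analytes patients x analytes numeric matrix, rows aligned with
#'   `patients` (checked against rownames when present).
#' @param label cohort label; `"RTBT2"`, `"RTBT3"` or `"RT3"`.
#' @return a [SASPCohort-class]
#' @export
SASPCohort <- function(patients, analytes, label) {
  analytes <- as.matrix(analytes)
  if (nrow(analytes) != nrow(patients))
    stop("analyte matrix must have one row per patient")
  if (!is.null(rownames(analytes)) &&
      !identical(rownames(analytes), as.character(patients$id)))
    stop("analyte matrix rownames must match patient ids")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = t(analytes)),
    colData = S4Vectors::DataFrame(patients, row.names = patients$id))
  new("SASPCohort", se, label = label)
}

#' Write a cohort to the two-file delimited interchange format
#'
#' `patients.csv` holds `id,age,stage,treatment,time,event`; `analytes.csv`
#' holds `id` plus one log2 column per analyte.
#' @param cohort a [SASPCohort-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the two file paths
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- patientData(cohort)
  keep <- intersect(c("id", "age", "stage", "treatment", "time", "event"),
                    colnames(pd))
  pf <- file.path(dir, sprintf("%s_patients.csv", cohortLabel(cohort)))
  af <- file.path(dir, sprintf("%s_analytes.csv", cohortLabel(cohort)))
  write.csv(.signif_df(pd[, keep]), pf, row.names = FALSE, quote = FALSE)
  am <- analyteMatrix(cohort)
  write.csv(.signif_df(data.frame(id = rownames(am), am, check.names = FALSE)),
            af, row.names = FALSE, quote = FALSE)
  invisible(c(patients = pf, analytes = af))
}

#' Read a cohort from the delimited interchange format
#' @param patientsPath,analytesPath CSV paths as written by [writeCohortCSV()]
#' @param label cohort label
#' @export
readCohortCSV <- function(patientsPath, analytesPath, label) {
  patients <- read.csv(patientsPath, stringsAsFactors = FALSE)
  adf <- read.csv(analytesPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(as.character(adf$id), as.character(patients$id)))
    stop("patients and analytes files disagree on ids")
  analytes <- as.matrix(adf[, setdiff(colnames(adf), "id"), drop = FALSE])
  rownames(analytes) <- adf$id
  SASPCohort(patients, analytes, label)
}

#' Simulate a raw multiplex bead-array plate
#'
#' Emits one table of wells per analyte: a serial-dilution standard series
#' with known concentrations plus replicated sample wells. Median
#' fluorescence follows a monotone log2-log2 standard curve
#' `log2(MFI) = intercept + slope * log2(conc)` plus Gaussian noise; bead
#' counts are Poisson. Ground-truth concentrations are retained in
#' `known_conc` for recovery tests.
#'
#' @param config a `SASPSimConfig` (analyte names and log2 levels are reused
#'   for the sample wells).
#' @param nStandards number of standard-dilution points (>= 4).
#' @param nReplicates replicate wells per sample.
#' @param nSamples sample wells per analyte.
#' @param noiseSd Gaussian noise sd on log2(MFI).
#' @param beadMean Poisson mean bead count per well.
#' @param curveIntercept,curveSlope the generating standard curve.
#' @param topConc,dilutionFactor standard series: `topConc / dilutionFactor^k`.
#' @param seed integer.
#' @return data.frame with columns `well`, `analyte`, `mfi`, `bead_count`,
#'   `replicate`, `is_standard`, `known_conc`.
#' @export
simulatePlate <- function(config, nStandards = 8, nReplicates = 2,
                          nSamples = 24, noiseSd = 0.05, beadMean = 80,
                          curveIntercept = 2, curveSlope = 0.9,
                          topConc = 10000, dilutionFactor = 4, seed = 1L) {
  stopifnot(inherits(config, "SASPSimConfig"))
  if (nStandards < 4) stop("nStandards must be >= 4")
  .with_seed(seed, {
    rows <- lapply(config$analyteNames, function(a) {
      std_conc <- topConc / dilutionFactor^(seq_len(nStandards) - 1)
      samp_log2 <- rnorm(nSamples, config$analyteMeans[[a]], config$analyteSds[[a]])
      conc <- c(rep(std_conc, each = nReplicates),
                rep(2^samp_log2, each = nReplicates))
      is_std <- rep(c(rep(TRUE, nStandards), rep(FALSE, nSamples)),
                    each = nReplicates)
      grp <- rep(sprintf("%s_%s%02d", a,
                         c(rep("std", nStandards), rep("s", nSamples)),
                         c(seq_len(nStandards), seq_len(nSamples))),
                 each = nReplicates)
      log2_mfi <- curveIntercept + curveSlope * log2(conc) +
        rnorm(length(conc), 0, noiseSd)
      data.frame(
        well = sprintf("%s_w%03d", a, seq_along(conc)),
        analyte = a, mfi = 2^log2_mfi,
        bead_count = rpois(length(conc), beadMean),
        replicate = grp, is_standard = is_std,
        known_conc = conc, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
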