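#' @include interaction.R
NULL

# floats written at 6 significant digits for bit-stable delimited output
.signif_df <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

.write_csv6 <- function(df, path) {
  write.csv(.signif_df(as.data.frame(df)), path, row.names = FALSE, quote = FALSE)
  path
}

#' Export a Kaplan-Meier curve as CSV
#'
#' Columns `time`, `at_risk`, `events`, `censored`, `survival`; floats at 6
#' significant digits. Re-exporting identical data yields a byte-identical
#' file.
#' @param curve a `kmCurve` from [kmEstimate()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportKM <- function(curve, path) invisible(.write_csv6(curve, path))

#' Export a vote matrix as CSV (models x patients, 0/1)
#' @param votes matrix from [buildVoteMatrix()].
#' @param path output CSV path.
#' @export
exportVoteMatrix <- function(votes, path) {
  df <- data.frame(model_id = rownames(votes), votes, check.names = FALSE)
  invisible(.write_csv6(df, path))
}

.record_row <- function(r) {
  se <- r@splitEval
  row <- data.frame(
    model_id = r@model@modelId,
    n_proteins = length(r@model@proteins),
    proteins = paste(r@model@proteins, collapse = ";"),
    lambda = r@model@fit@lambda,
    cutoff_value = r@model@cutoffValue,
    train_hr = se$train$hr, train_p = se$train$p,
    test_hr = se$test$hr, test_p = se$test$p,
    stringsAsFactors = FALSE)
  if (length(r@bootstrap)) {
    b <- r@bootstrap
    row$boot_mean_hr <- b$mean_hr
    row$boot_p_gt_0.05 <- b$bins[["p_gt_0.05"]]
    row$boot_p_0.001_0.05 <- b$bins[["p_0.001_0.05"]]
    row$boot_p_le_0.001 <- b$bins[["p_le_0.001"]]
    row$boot_pass <- b$pass
  } else {
    row[c("boot_mean_hr", "boot_p_gt_0.05", "boot_p_0.001_0.05",
          "boot_p_le_0.001")] <- NA_real_
    row$boot_pass <- NA
  }
  if (nrow(r@external)) {
    for (i in seq_len(nrow(r@external))) {
      lab <- r@external$cohort[i]
      row[[paste0(lab, "_hr")]] <- r@external$hr[i]
      row[[paste0(lab, "_ci_lo")]] <- r@external$ci_lo[i]
      row[[paste0(lab, "_ci_hi")]] <- r@external$ci_hi[i]
      row[[paste0(lab, "_p")]] <- r@external$p[i]
    }
  }
  row
}

#' Export an ensemble model table as CSV
#'
#' One row per record with train/test HRs and p-values, bootstrap summary
#' (mean HR and the three p-value bins) and external-validation columns -
#' the flat layout of the published model tables. An empty record list
#' yields a header-only file.
#'
#' @param records list of [ModelRecord-class].
#' @param path output CSV path.
#' @export
exportModelTable <- function(records, path) {
  if (!length(records)) {
    header <- c("model_id", "n_proteins", "proteins", "lambda", "cutoff_value",
                "train_hr", "train_p", "test_hr", "test_p", "boot_mean_hr",
                "boot_p_gt_0.05", "boot_p_0.001_0.05", "boot_p_le_0.001",
                "boot_pass")
    writeLines(paste(header, collapse = ","), path)
    return(invisible(path))
  }
  rows <- lapply(records, .record_row)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  invisible(.write_csv6(do.call(rbind, rows), path))
}

#' Serialize model records as JSON lines
#'
#' One JSON object per line per record: proteins, coefficients with the
#' frozen standardization, penalty, cutoff, split/bootstrap/external
#' summaries. Sufficient to re-apply a model to new data.
#' @param records list of [ModelRecord-class].
#' @param path output path.
#' @export
writeModelRecords <- function(records, path) {
  lines <- vapply(records, function(r) {
    m <- r@model
    jsonlite::toJSON(list(
      model_id = m@modelId, proteins = m@proteins,
      beta = as.list(m@fit@beta), center = as.list(m@fit@center),
      scale = as.list(m@fit@scale), lambda = m@fit@lambda,
      ties = m@fit@ties, family = m@fit@family,
      cutoff_percentile = m@cutoffPercentile, cutoff_value = m@cutoffValue,
      orientation_flipped = m@orientationFlipped, train_label = m@trainLabel,
      split_eval = r@splitEval, bootstrap = r@bootstrap,
      external = r@external), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `inputDir` (cohort CSVs as written by [writeCohortCSV()])
#' or `simulation` (a `SASPSimConfig`) must be provided.
#'
#' @param simulation a `SASPSimConfig`, or NULL.
#' @param inputDir directory of `<label>_patients.csv` / `<label>_analytes.csv`
#'   files, or NULL.
#' @param panel panel preset name or protein vector (see [saspPanel()]).
#' @param ensembleCohort label of the cohort the ensemble trains on.
#' @param nPairs,nBoot,subsampleFraction,cutoffPercentile,hrMin,pMax,maxModels
#'   ensemble parameters.
#' @param lambda `"cv"` or numeric.
#' @param horizon administrative censoring horizon (years).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simulation = NULL, inputDir = NULL, panel = "p8",
                           ensembleCohort = "RTBT2", nPairs = 200,
                           nBoot = 200, subsampleFraction = 70,
                           cutoffPercentile = 40, hrMin = 3.0, pMax = 0.05,
                           maxModels = 25, lambda = "cv", horizon = 5,
                           seed = 1L) {
  if (is.null(simulation) == is.null(inputDir))
    stop("provide exactly one of 'simulation' or 'inputDir'")
  if (!is.null(simulation)) stopifnot(inherits(simulation, "SASPSimConfig"))
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipelineConfig()]; a `simulation`
#' block is passed to [simConfig()].
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    sim <- y$simulation
    if (!is.null(sim$groupSizes)) sim$groupSizes <- unlist(sim$groupSizes)
    y$simulation <- do.call(simConfig, sim)
  }
  do.call(pipelineConfig, y)
}

.load_cohorts <- function(config, seed) {
  if (!is.null(config$simulation)) {
    simulateCohorts(config$simulation, seed = seed)
  } else {
    pats <- list.files(config$inputDir, pattern = "_patients\\.csv$",
                       full.names = TRUE)
    if (!length(pats))
      stop("dependency error: no '<label>_patients.csv' files in ", config$inputDir)
    out <- lapply(pats, function(pf) {
      af <- sub("_patients\\.csv$", "_analytes.csv", pf)
      if (!file.exists(af)) stop("dependency error: missing file ", af)
      label <- sub("_patients\\.csv$", "", basename(pf))
      readCohortCSV(pf, af, label)
    })
    names(out) <- vapply(out, cohortLabel, character(1))
    out
  }
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - simulate/load, horizon censoring, quartile
#' screening, split-pair ensemble with selection, bootstrap and external
#' validation, consensus voting, stratified brachytherapy analysis, and
#' multifactorial stage x SASP x treatment survival summaries - writing every
#' table to `outdir` plus a JSON manifest with per-file MD5 checksums and an
#' overall manifest hash. Outputs are write-once; re-running with the same
#' configuration and seed reproduces the manifest hash exactly.
#'
#' @param config a `pipelineConfig` (or path to a YAML file).
#' @param outdir output directory (must not already contain a manifest).
#' @param seed master seed, overriding `config$seed` when given.
#' @return the manifest, invisibly (list with `files`, `hash`, `seeds`).
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(seed)) seed <- config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(outdir, "manifest.json")))
    stop("outdir already contains a completed run (write-once layout): ", outdir)
  stage_seed <- function(k) .derive_seed(seed, 1000 * k)
  paths <- character()
  emit <- function(p) { paths[[basename(p)]] <<- p; p }

  ## stage 1: cohorts
  cohorts <- .load_cohorts(config, stage_seed(1))

  ## stage 2: preprocessing (administrative censoring at the horizon)
  cohorts <- lapply(cohorts, function(co) {
    pd <- patientData(co)
    ce <- censorAtHorizon(pd$time, pd$event, config$horizon)
    pd$time <- ce$time; pd$event <- ce$event
    SASPCohort(pd, analyteMatrix(co), cohortLabel(co))
  })
  for (co in cohorts) {
    fp <- writeCohortCSV(co, outdir)
    emit(fp[["patients"]]); emit(fp[["analytes"]])
  }

  ## stage 3: quartile screening
  proteins <- rownames(cohorts[[1]])
  screen <- screenPanel(cohorts, proteins)
  emit(.write_csv6(screen, file.path(outdir, "quartile_screen.csv")))

  ## stage 4: ensemble
  train_label <- config$ensembleCohort
  if (!train_label %in% names(cohorts))
    stop("dependency error: ensemble cohort ", train_label, " not among inputs")
  panel <- saspPanel(config$panel)
  records <- runEnsemble(cohorts[[train_label]], panel, nPairs = config$nPairs,
                         cutoffPercentile = config$cutoffPercentile,
                         lambda = config$lambda, seed = stage_seed(4))
  selected <- selectModels(records, hrMin = config$hrMin, pMax = config$pMax,
                           maxModels = config$maxModels)
  others <- cohorts[setdiff(names(cohorts), train_label)]
  selected <- lapply(seq_along(selected), function(i) {
    r <- selected[[i]]
    r@bootstrap <- bootstrapValidate(r@model, cohorts[[train_label]],
                                     nBoot = config$nBoot,
                                     subsampleFraction = config$subsampleFraction,
                                     seed = .derive_seed(stage_seed(4), i))
    if (length(others)) r@external <- externalValidate(r@model, unname(others))
    validObject(r)
    r
  })
  if (length(selected))  # re-sort by bootstrap performance now that it is known
    selected <- selectModels(selected, hrMin = config$hrMin,
                             pMax = config$pMax, maxModels = config$maxModels)
  emit(exportModelTable(selected, file.path(outdir, "models.csv")))
  emit(writeModelRecords(selected, file.path(outdir, "models.jsonl")))

  ## stage 5: consensus voting on the training cohort
  consensus <- NULL
  if (length(selected)) {
    votes <- buildVoteMatrix(selected, cohorts[[train_label]])
    emit(exportVoteMatrix(votes, file.path(outdir, "vote_matrix.csv")))
    consensus <- consensusVote(votes)
    emit(.write_csv6(consensus, file.path(outdir, "consensus.csv")))
  }

  ## stage 6: brachytherapy benefit within SASP strata (stage III pool)
  stage3 <- cohorts[vapply(cohorts, function(co)
    all(patientData(co)$stage == "III"), logical(1))]
  arms <- unique(unlist(lapply(stage3, function(co) patientData(co)$treatment)))
  if (length(selected) && length(stage3) && length(arms) == 2) {
    emit(.write_csv6(btEffectTable(selected, unname(stage3)),
                     file.path(outdir, "bt_by_model.csv")))
    s3_votes <- buildVoteMatrix(selected,
                                do.call(rbind, lapply(unname(stage3), analyteMatrix)))
    s3_cons <- consensusVote(s3_votes)
    s3_rows <- stratifiedBtEffect(unname(stage3),
                                  setNames(s3_cons$ternary, s3_cons$patient),
                                  nModels = length(selected))
    emit(.write_csv6(s3_rows, file.path(outdir, "bt_consensus.csv")))
  }

  ## stage 7: multifactorial strata across all cohorts
  if (length(selected)) {
    all_votes <- buildVoteMatrix(selected,
                                 do.call(rbind, lapply(unname(cohorts), analyteMatrix)))
    all_cons <- consensusVote(all_votes)
    mf <- multifactorStrata(unname(cohorts),
                            setNames(all_cons$ternary, all_cons$patient),
                            horizon = config$horizon)
    emit(.write_csv6(mf$categories, file.path(outdir, "multifactor.csv")))
    for (nm in names(mf$curves))
      emit(exportKM(mf$curves[[nm]], file.path(outdir, paste0("km_", nm, ".csv"))))
  }

  ## manifest
  md5 <- tools::md5sum(unlist(paths))
  files <- data.frame(file = basename(names(md5)), md5 = unname(md5),
                      stringsAsFactors = FALSE)
  files <- files[order(files$file), ]
  params <- config
  params$simulation <- if (!is.null(config$simulation)) unclass(config$simulation)
  hash_input <- jsonlite::toJSON(
    list(params = unclass(params), seed = seed, files = files),
    auto_unbox = TRUE, digits = NA)
  tmp <- file.path(outdir, ".manifest_body")
  writeLines(hash_input, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(seed = seed,
                   seeds = setNames(vapply(1:7, stage_seed, numeric(1)),
                                    paste0("stage", 1:7)),
                   n_selected = length(selected),
                   files = files, hash = hash)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(outdir, "manifest.json"))
  invisible(manifest)
}
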