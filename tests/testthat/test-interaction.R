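stage3_sim <- function(seed, ...) {
  cohorts <- simulateCohorts(simConfigSignal(
    3.5, groupSizes = c(RTBT3 = 150L, RT3 = 80L), ...), seed = seed)
  unname(cohorts)
}

test_that("ensemble-size p adjustment reproduces the printed arithmetic", {
  expect_equal(adjustPvalues(0.052, 25), 1.30)
  expect_equal(adjustPvalues(0.338, 25), 8.45)
  expect_equal(adjustPvalues(0, 7), 0)
  # uncapped by default, capped and Holm variants available
  expect_gt(adjustPvalues(0.2, 25), 1)
  expect_identical(adjustPvalues(0.2, 25, method = "bonferroni"), 1)
  expect_identical(adjustPvalues(c(0.01, 0.04), 2, method = "holm"),
                   p.adjust(c(0.01, 0.04), "holm"))
  expect_error(adjustPvalues(1.2, 5), "p")
})

test_that("stratified BT analysis recovers an interaction confined to high senescence", {
  # per-seed pattern: the high-SASP stratum detects the no-BT harm, the
  # low-SASP stratum shows the weaker (often null) effect; aggregated over
  # seeds to tolerate sampling noise
  h_sig <- 0; l_weaker <- 0
  for (s in c(71, 72, 73)) {
    cohorts <- stage3_sim(seed = s)
    m <- trainModel(cohorts[[1]], saspPanel("p8"), cutoffPercentile = 60,
                    seed = 1, modelId = 1L)
    rows <- stratifiedBtEffect(cohorts, m, nModels = 25)
    expect_setequal(rows$stratum, c("SASP_L", "SASP_H"))
    h <- rows[rows$stratum == "SASP_H", ]
    l <- rows[rows$stratum == "SASP_L", ]
    h_sig <- h_sig + (h$hr > 1 && h$p < 0.05)
    l_weaker <- l_weaker + (l$p > 0.05 || l$hr < h$hr)
    expect_equal(rows$adj_p, rows$p * 25)
    expect_identical(sum(rows$n_bt + rows$n_nobt), 230L)
  }
  expect_gte(h_sig, 2)
  expect_gte(l_weaker, 2)

  cohorts <- stage3_sim(seed = 71)
  m <- trainModel(cohorts[[1]], saspPanel("p8"), cutoffPercentile = 60,
                  seed = 1, modelId = 1L)
  rows <- stratifiedBtEffect(cohorts, m, nModels = 25)
  h <- rows[rows$stratum == "SASP_H", ]

  # relabeling BT <-> no-BT inverts the hazard ratio
  flipped <- lapply(cohorts, function(co) {
    pd <- patientData(co)
    pd$treatment <- ifelse(pd$treatment == "EBRT", "EBRT+BT", "EBRT")
    lab <- if (cohortLabel(co) == "RT3") "RTBT3" else "RT3"
    pd$id <- sub("^(RTBT3|RT3)", lab, pd$id)
    am <- analyteMatrix(co); rownames(am) <- pd$id
    SASPCohort(pd, am, lab)
  })
  rows_f <- stratifiedBtEffect(flipped, m, nModels = 25)
  expect_equal(rows_f$hr[rows_f$stratum == "SASP_H"], 1 / h$hr, tolerance = 1e-6)
})

test_that("stage III restriction and single-arm strata are enforced", {
  cohorts <- simulateCohorts(small_cfg(), seed = 5)
  m <- trainModel(cohorts$RTBT3, saspPanel("p8"), seed = 2, modelId = 2L)
  expect_error(stratifiedBtEffect(unname(cohorts), m), "stage III")
  expect_error(stratifiedBtEffect(cohorts$RTBT3, m), "both treatment arms")
})

test_that("consensus-mode strata are disjoint, exhaustive, and include M", {
  cohorts <- stage3_sim(seed = 81)
  set.seed(81)
  models <- lapply(1:7, function(i)
    trainModel(cohorts[[1]], saspPanel(if (i %% 2) "p8" else "p7"),
               cutoffPercentile = 60,
               trainIdx = sample(150, 110), seed = i, modelId = i))
  am <- do.call(rbind, lapply(cohorts, analyteMatrix))
  cons <- consensusVote(buildVoteMatrix(models, am))
  labels <- setNames(cons$ternary, cons$patient)
  rows <- stratifiedBtEffect(cohorts, labels, nModels = length(models))
  expect_identical(sum(rows$n_bt + rows$n_nobt), 230L)
  expect_true(all(rows$stratum %in% c("SASP_L", "SASP_M", "SASP_H")))
  expect_equal(rows$adj_p / rows$p, rep(7, nrow(rows)))
})

test_that("per-model BT table multiplies p by the model count", {
  cohorts <- stage3_sim(seed = 91)
  set.seed(91)
  models <- lapply(1:3, function(i)
    trainModel(cohorts[[1]], saspPanel("p8"), cutoffPercentile = 60,
               trainIdx = sample(150, 110), seed = i, modelId = i))
  tab <- btEffectTable(models, cohorts)
  expect_setequal(unique(tab$model_id), 1:3)
  expect_equal(tab$adj_p, tab$p * 3)
})

test_that("pooled stage III HR lies within the mixture range of stratum HRs", {
  cohorts <- stage3_sim(seed = 101)
  m <- trainModel(cohorts[[1]], saspPanel("p8"), cutoffPercentile = 60,
                  seed = 3, modelId = 3L)
  rows <- stratifiedBtEffect(cohorts, m)
  pool <- do.call(rbind, lapply(cohorts, function(co)
    patientData(co)[, c("time", "event", "treatment")]))
  pooled <- coxFit(pool$time, pool$event,
                   cbind(no_bt = as.numeric(pool$treatment == "EBRT")))
  lo <- min(rows$hr) * 0.7; hi <- max(rows$hr) * 1.4
  expect_gt(pooled$hr[["no_bt"]], lo)
  expect_lt(pooled$hr[["no_bt"]], hi)
})

test_that("multifactor strata order categories by late survival", {
  cohorts <- simulateCohorts(simConfigSignal(3.5), seed = 111)
  set.seed(111)
  models <- lapply(1:5, function(i)
    trainModel(cohorts$RTBT2, saspPanel("p8"),
               trainIdx = sample(276, 200), seed = i, modelId = i))
  am <- do.call(rbind, lapply(unname(cohorts), analyteMatrix))
  cons <- consensusVote(buildVoteMatrix(models, am))
  mf <- multifactorStrata(unname(cohorts), setNames(cons$ternary, cons$patient))
  expect_true(all(c("category", "surv1", "surv_horizon") %in% colnames(mf$categories)))
  expect_identical(sum(mf$categories$n), 565L)
  # monotone generative effects: stage II / SASP_L / BT best, stage III /
  # SASP_H / no BT worst
  best <- mf$categories$category[1]
  worst <- mf$categories$category[nrow(mf$categories)]
  expect_identical(best, "RTBT2_L")
  expect_identical(worst, "RT3_H")
  expect_identical(length(mf$curves), nrow(mf$categories))

  # single category present: exactly one curve
  one <- multifactorStrata(cohorts$RT3,
                           setNames(rep("H", 86), patientData(cohorts$RT3)$id))
  expect_identical(names(one$curves), "RT3_H")
})
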