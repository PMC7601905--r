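test_that("Kaplan-Meier handles the no-event and all-event closed forms", {
  all_cens <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  km <- kmEstimate(1:4, rep(1, 4))
  expect_equal(km$survival, c(3 / 4, 1 / 2, 1 / 4, 0))

  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier matches the brute-force product over risk sets", {
  set.seed(101)
  for (i in 1:25) {
    inst <- random_instance()
    km <- kmEstimate(inst$time, inst$event)
    oracle <- brute_km(inst$time, inst$event)
    expect_equal(km$survival, oracle$survival[match(km$time, oracle$time)],
                 tolerance = 1e-10)
    # probabilities non-increasing, drops only at event times
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival[km$events == 0] ==
                    c(1, km$survival)[which(km$events == 0)]))
  }
  # large-sample agreement with the true exponential curve
  set.seed(7)
  tt <- rexp(200, 0.5)
  km <- kmEstimate(tt, rep(1, 200))
  expect_lt(max(abs(km$survival - exp(-0.5 * km$time))[km$time < 6]), 0.12)
})

test_that("log-rank agrees with the O-E/V hand computation and is symmetric", {
  # 6-patient instance worked by hand through the risk-set table
  tt <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 1, 1, 0, 1)
  gr <- c("a", "b", "a", "b", "a", "b")
  got <- logrankTest(tt, ev, gr)
  oracle <- brute_logrank(tt, ev, gr)
  expect_equal(got$chi2, oracle$chi2, tolerance = 1e-10)
  expect_equal(got$p, oracle$p, tolerance = 1e-10)

  set.seed(17)
  for (i in 1:20) {
    inst <- random_instance()
    if (length(unique(inst$group)) < 2) next
    got <- logrankTest(inst$time, inst$event, inst$group)
    oracle <- brute_logrank(inst$time, inst$event, inst$group)
    expect_equal(got$chi2, oracle$chi2, tolerance = 1e-8)
    # label symmetry
    flipped <- logrankTest(inst$time, inst$event,
                           ifelse(inst$group == "a", "b", "a"))
    expect_equal(flipped$chi2, got$chi2, tolerance = 1e-12)
  }

  # identical groups differ only by label: statistic 0 ... via zero events
  expect_identical(logrankTest(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 1, 2, 2)),
                   list(chi2 = 0, p = 1))
})

test_that("Cox fit matches grid-search maximization of the partial likelihood", {
  # the worked 4-patient instance
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  fit <- coxFit(tt, ev, cbind(x = x))
  expect_equal(unname(fit$beta), brute_cox_beta(tt, ev, x), tolerance = 1e-4)

  set.seed(23)
  n_checked <- 0
  for (i in 1:40) {
    inst <- random_instance()
    fit <- tryCatch(suppressWarnings(coxFit(inst$time, inst$event,
                                            cbind(x = inst$x))),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    for (ties in c("efron", "breslow")) {
      f <- coxFit(inst$time, inst$event, cbind(x = inst$x), ties = ties)
      expect_equal(unname(f$beta),
                   brute_cox_beta(inst$time, inst$event, inst$x, ties = ties),
                   tolerance = 1e-4)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("Cox summaries satisfy their structural invariants", {
  set.seed(3)
  tt <- rexp(60, 0.3); ev <- rbinom(60, 1, 0.7); x <- rnorm(60)
  fit <- coxFit(tt, ev, cbind(x = x))
  expect_equal(unname(fit$hr), exp(unname(fit$beta)))
  expect_true(fit$ci_lo[["x"]] < fit$hr[["x"]] && fit$hr[["x"]] < fit$ci_hi[["x"]])
  expect_true(fit$p[["x"]] >= 0 && fit$p[["x"]] <= 1)

  # constant covariate: no contrast, beta 0
  const <- coxFit(tt, ev, cbind(x = rep(1, 60)))
  expect_equal(unname(const$beta), 0, tolerance = 1e-8)

  # monotone likelihood: perfect separation flagged
  expect_warning(sep <- coxFit(c(1, 2), c(1, 1), cbind(x = c(1, 0))),
                 "monotone|capped")
  expect_false(sep$converged)
  expect_lte(max(abs(sep$beta)), 15)
  expect_error(coxFit(c(1, 2), c(0, 0), cbind(x = c(1, 0))), "no events")
})

test_that("two-group Cox Wald and log-rank tests agree asymptotically", {
  # moderate effect keeps the p-values away from the extreme tail, where the
  # two chi-square statistics (and hence the p-values) are asymptotically
  # equivalent; compare the statistics at 20% relative tolerance
  cfg <- simConfigSignal(1.8, groupSizes = c(RTBT2 = 300L))
  co <- simulateCohorts(cfg, seed = 12)$RTBT2
  pd <- patientData(co)
  grp <- pd$latent_z > median(pd$latent_z)
  fit <- coxFit(pd$time, pd$event, cbind(g = as.numeric(grp)))
  wald_chi2 <- (fit$beta[["g"]] / fit$se[["g"]])^2
  lr <- logrankTest(pd$time, pd$event, grp)
  expect_lt(abs(wald_chi2 / lr$chi2 - 1), 0.2)
  expect_lt(abs(fit$p[["g"]] / lr$p - 1), 0.35)
})

test_that("ridge fit reduces to the unpenalized fit at lambda 0 and shrinks", {
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  r0 <- ridgeCoxFit(cbind(x = x), tt, ev, lambda = 0)
  # compare on the standardized scale used by the ridge fit
  expect_equal(unname(r0@beta) / sd(x),
               brute_cox_beta(tt, ev, x), tolerance = 1e-4)

  set.seed(31)
  n <- 80; X <- matrix(rnorm(n * 4), n, 4); colnames(X) <- paste0("v", 1:4)
  tt <- rexp(n, 0.2 * exp(0.6 * X[, 1])); ev <- rbinom(n, 1, 0.8)
  r0 <- ridgeCoxFit(X, tt, ev, lambda = 0)
  cf <- suppressWarnings(coxFit(tt, ev, scale(X)))
  expect_equal(unname(r0@beta), unname(cf$beta), tolerance = 1e-6)

  # heavy penalty sends coefficients to zero
  rbig <- ridgeCoxFit(X, tt, ev, lambda = 1e8)
  expect_lt(max(abs(rbig@beta)), 1e-4)

  # penalty symmetry: duplicated columns share the coefficient
  Xd <- cbind(a = X[, 1], b = X[, 1])
  rd <- ridgeCoxFit(Xd, tt, ev, lambda = 5)
  expect_equal(rd@beta[["a"]], rd@beta[["b"]], tolerance = 1e-6)

  # coefficient norm monotone non-increasing along the penalty path
  for (s in 1:5) {
    set.seed(s)
    Xs <- matrix(rnorm(60 * 3), 60, 3)
    ts <- rexp(60, 0.3); es <- rbinom(60, 1, 0.7)
    norms <- vapply(c(0.01, 0.1, 1, 10, 100, 1000), function(l)
      sqrt(sum(ridgeCoxFit(Xs, ts, es, lambda = l)@beta^2)), numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("ridge fit agrees with independent penalized implementations", {
  skip_if_not_installed("glmnet")
  set.seed(44)
  n <- 150; X <- matrix(rnorm(n * 5), n, 5); colnames(X) <- paste0("v", 1:5)
  tt <- round(rexp(n, 0.2 * exp(0.5 * X[, 1])), 1) + 0.05
  ev <- rbinom(n, 1, 0.7)
  lam <- 4
  # survival::coxph with a ridge penalty (Efron ties, same objective)
  xs <- scale(X)
  cp <- survival::coxph(survival::Surv(tt, ev) ~
                          survival::ridge(xs, theta = lam, scale = FALSE),
                        ties = "efron")
  mine <- ridgeCoxFit(X, tt, ev, lambda = lam, ties = "efron")
  expect_equal(unname(mine@beta), unname(coef(cp)), tolerance = 1e-8)
  # glmnet's coxnet (Breslow ties, penalty scaled by n)
  g <- glmnet::glmnet(xs, survival::Surv(tt, ev), family = "cox", alpha = 0,
                      standardize = FALSE, lambda = c(10, 2, 1) * lam / n,
                      thresh = 1e-14)
  mineb <- ridgeCoxFit(X, tt, ev, lambda = lam, ties = "breslow")
  expect_equal(unname(mineb@beta), as.numeric(coef(g, s = lam / n)),
               tolerance = 1e-5)
})

test_that("cross-validated penalty selection shrinks under noise, relaxes under signal", {
  grid <- exp(seq(log(1e3), log(1e-3), length.out = 20))
  one <- cvLambdaMin(matrix(rnorm(200), 100, 2), rexp(100, 0.3),
                     rbinom(100, 1, 0.6), lambdaGrid = 5, seed = 1)
  expect_identical(one$lambda, 5)

  upper_null <- 0; lower_sig <- 0
  for (s in 1:10) {
    set.seed(s)
    Xn <- matrix(rnorm(200 * 5), 200, 5)
    tn <- rexp(200, 0.3); en <- rbinom(200, 1, 0.7)
    ln <- cvLambdaMin(Xn, tn, en, lambdaGrid = grid, seed = s)$lambda
    upper_null <- upper_null + (ln >= median(grid))

    Xs <- matrix(rnorm(400), 400, 1)
    ts <- rexp(400, 0.2 * exp(1.5 * Xs[, 1])); es <- rep(1, 400)
    ls <- cvLambdaMin(Xs, ts, es, lambdaGrid = grid, seed = s)$lambda
    lower_sig <- lower_sig + (ls <= median(grid))
  }
  expect_gte(upper_null, 8)
  expect_gte(lower_sig, 8)
})

test_that("linear predictor uses the frozen training standardization", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4); colnames(X) <- paste0("v", 1:4)
  tt <- rexp(50, 0.3); ev <- rbinom(50, 1, 0.8)
  fit <- ridgeCoxFit(X, tt, ev, lambda = 1)

  expect_equal(unname(linearPredictor(fit, X)),
               drop(scale(X) %*% fit@beta), tolerance = 1e-12)
  # zero model gives zero scores
  f0 <- fit; f0@beta[] <- 0
  expect_true(all(linearPredictor(f0, X) == 0))
  # pointwise: duplicated rows give duplicated scores
  s2 <- linearPredictor(fit, X[c(1, 1, 2), ])
  expect_identical(s2[1], s2[2])
  # shifting a covariate at application time shifts scores (no re-centering)
  Xshift <- X; Xshift[, 1] <- Xshift[, 1] + 10
  expect_false(isTRUE(all.equal(linearPredictor(fit, X),
                                linearPredictor(fit, Xshift))))
  expect_error(linearPredictor(fit, X[, 1:2]), "missing covariates")
})
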