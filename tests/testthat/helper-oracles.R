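# Brute-force oracles built by direct enumeration over risk sets; kept
# deliberately independent of the package implementation (no survival::
# calls) so engine tests are genuine dual-route checks.

# product-limit estimator by explicit risk-set counting
brute_km <- function(time, event) {
  ts <- sort(unique(time))
  S <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    if (d > 0) S <- S * (1 - d / at_risk)
    surv[i] <- S
  }
  data.frame(time = ts, survival = surv)
}

# two-group log-rank from the hand-tabulated O-E / V risk-set table
brute_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# partial log-likelihood by explicit enumeration (single or multi covariate)
brute_cox_loglik <- function(beta, time, event, x, ties = "efron") {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    deaths <- which(time == t & event == 1)
    d <- length(deaths)
    ll <- ll + sum(eta[deaths])
    for (r in seq_len(d) - 1) {
      phi <- if (ties == "efron") r / d else 0
      ll <- ll - log(sum(w[risk]) - phi * sum(w[deaths]))
    }
  }
  ll
}

# grid/golden-section maximizer of the single-covariate partial likelihood
brute_cox_beta <- function(time, event, x, ties = "efron", interval = c(-8, 8)) {
  optimize(function(b) brute_cox_loglik(b, time, event, x, ties),
           interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# random small survival instances (<= 8 patients, ties possible)
random_instance <- function(n = NULL, tie_prob = 0.3) {
  if (is.null(n)) n <- sample(4:8, 1)
  tt <- sample(1:5, n, replace = TRUE) + ifelse(runif(n) < tie_prob, 0, runif(n))
  ev <- rbinom(n, 1, 0.7)
  if (sum(ev) == 0) ev[sample(n, 2)] <- 1
  list(time = tt, event = ev, x = round(rnorm(n), 2),
       group = sample(c("a", "b"), n, replace = TRUE))
}

# small cohorts used across tests
small_cfg <- function(...) {
  simConfig(groupSizes = c(RTBT2 = 80L, RTBT3 = 60L, RT3 = 40L), ...)
}
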