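test_that("Metropolis-Hastings recovers a known Gaussian target", {
  # 2-D correlated Gaussian; mean and SD recovered within Monte-Carlo error
  S <- matrix(c(1, 0.6, 0.6, 2), 2, 2)
  Sinv <- solve(S)
  mu <- c(1, -2)
  nld <- function(x) 0.5 * drop(t(x - mu) %*% Sinv %*% (x - mu))
  res <- mh_sample(nld, start = c(0, 0), proposal_cov = S * 2.4^2 / 2,
                   n_total = 50000, thin = 5, burn_in = 5000, seed = 4)
  expect_equal(nrow(res$samples), 9000)
  expect_gt(res$acceptance_rate, 0.1)
  expect_lt(res$acceptance_rate, 0.6)
  ess <- apply(res$samples, 2, function(x) {
    unname(coda::effectiveSize(coda::mcmc(x)))
  })
  for (j in 1:2) {
    mcse <- sqrt(S[j, j] / ess[j])
    expect_lt(abs(mean(res$samples[, j]) - mu[j]), 3 * mcse)
    sd_se <- sqrt(S[j, j]) / sqrt(2 * ess[j])
    expect_lt(abs(sd(res$samples[, j]) - sqrt(S[j, j])), 3 * sd_se)
  }
  # determinism under the seed
  res2 <- mh_sample(nld, start = c(0, 0), proposal_cov = S * 2.4^2 / 2,
                    n_total = 50000, thin = 5, burn_in = 5000, seed = 4)
  expect_identical(res$samples, res2$samples)
  expect_error(mh_sample(nld, c(0, 0), matrix(c(1, 2, 2, 1), 2, 2)),
               "degenerate proposal")
})

test_that("thinning bookkeeping matches the save-every-k convention", {
  nld <- function(x) 0.5 * sum(x^2)
  res <- mh_sample(nld, 0, matrix(1), n_total = 10000, thin = 20,
                   burn_in = 1000, seed = 1, adapt = FALSE)
  expect_equal(nrow(res$samples), floor((10000 - 1000) / 20))
  # the full-scale arithmetic: 10 million total, thin 2000 -> 5000 saved
  expect_equal(floor((10e6 - 0) / 2000), 5000)
})

test_that("asymptotic intervals match a parametric bootstrap", {
  fit <- default_cfgI_fit()
  ai <- asymptotic_intervals(fit, derived = c("b0", "ssb_2015",
                                              "recruits_2015"))
  expect_equal(nrow(ai), 48 + 3)
  expect_true(all(ai$sd > 0))
  expect_true(all(ai$lower <= ai$estimate & ai$estimate <= ai$upper))
  # bootstrap oracle: draw from the Gaussian approximation on the
  # estimation scale and propagate through the model
  set.seed(99)
  cov_t <- solve(fit$hessian)
  L <- chol(cov_t)
  draws <- matrix(rnorm(500 * nrow(cov_t)), 500) %*% L
  ssb <- apply(draws, 1, function(d) {
    rep <- krillphase:::replay_fit(fit, fit$t_hat + d)
    rep$SSB[match(2015, fit$data$years)]
  })
  sd_boot <- sd(ssb)
  sd_delta <- ai$sd[ai$quantity == "ssb_2015"]
  expect_lt(abs(sd_boot - sd_delta) / sd_delta, 0.05 + 3 / sqrt(2 * 500))
})

test_that("delta and MCMC uncertainty agree on a quadratic objective", {
  # Gaussian (quadratic NLL) case: the asymptotic SD is exact, so the
  # MCMC posterior SD must match it closely at this chain length
  S <- matrix(c(0.5, 0.2, 0.2, 1.5), 2, 2)
  Sinv <- solve(S)
  nld <- function(x) 0.5 * drop(t(x) %*% Sinv %*% x)
  res <- mh_sample(nld, c(0, 0), S * 2.4^2 / 2, n_total = 50000, thin = 2,
                   burn_in = 5000, seed = 8)
  sd_mcmc <- apply(res$samples, 2, sd)
  sd_delta <- sqrt(diag(S))  # inverse Hessian of the quadratic
  expect_lt(max(abs(sd_mcmc - sd_delta) / sd_delta), 0.05)
})

test_that("non-invertible fits refuse asymptotic and MCMC machinery", {
  fit <- default_cfgI_fit()
  broken <- fit
  broken$pd_hessian <- FALSE
  expect_error(asymptotic_intervals(broken), "not invertible")
  expect_error(mcmc_sample(broken), "not positive definite")
})

test_that("Heidelberger-Welch separates stationary from trended chains", {
  pass <- 0L
  for (s in 1:20) {
    set.seed(s)
    hw <- heidelberger_welch(rnorm(5000))
    pass <- pass + hw$stationarity_pass
  }
  expect_gte(pass, 18)  # 5% level null behaviour
  set.seed(1)
  trended <- rnorm(5000) + seq(0, 3, length.out = 5000)
  expect_false(heidelberger_welch(trended)$stationarity_pass)
  # constant chain: halfwidth undefined, flagged not failed
  hc <- heidelberger_welch(rep(2, 500))
  expect_true(hc$stationarity_pass)
  expect_true(is.na(hc$halfwidth_pass))
  expect_match(hc$note, "constant")
  # exactly mean-zero chain exercises the division guard
  set.seed(2)
  z <- rnorm(1000)
  z <- z - mean(z)
  hz <- heidelberger_welch(z)
  expect_true(is.na(hz$halfwidth_pass) || isFALSE(hz$halfwidth_pass))
})

test_that("Geweke scores, autocorrelation and effective size behave", {
  inside <- 0L
  for (s in 1:20) {
    set.seed(s)
    g <- geweke_and_acf(rnorm(5000))
    inside <- inside + (abs(g$z) < 1.96)
  }
  expect_gte(inside, 18)
  # AR(1): effective size close to the closed form n (1 - rho) / (1 + rho)
  set.seed(11)
  n <- 20000; rho <- 0.9
  ar1 <- as.numeric(arima.sim(list(ar = rho), n))
  g <- geweke_and_acf(ar1)
  expect_lt(abs(g$ess - n * (1 - rho) / (1 + rho)) /
              (n * (1 - rho) / (1 + rho)), 0.25)
  # duplicating every value forces lag-1 autocorrelation toward its
  # theoretical value 1/2 (from below, by the finite-sample n divisor)
  dup <- rep(rnorm(500), each = 2)
  expect_gte(geweke_and_acf(dup)$acf$autocorrelation[1], 0.45)
})

test_that("the diagnostics report aggregates per-quantity passes", {
  set.seed(21)
  chains <- cbind(a = rnorm(2000, mean = 50),
                  b = rnorm(2000, mean = -10))
  rep <- diagnostics_report(chains)
  expect_true(rep$pass)
  expect_equal(nrow(rep$table), 2)
  chains_bad <- cbind(chains,
                      c = rnorm(2000) + seq(0, 4, length.out = 2000))
  expect_false(diagnostics_report(chains_bad)$pass)
})
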