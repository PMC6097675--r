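test_that("lognormal NLL is a deviance with minimum at the observation", {
  expect_equal(lognormal_nll(100, 100, 0.3),
               0.5 * log(log(1 + 0.09)))
  # single point against an independent density evaluation: our deviance
  # drops log(obs) + 0.5 log(2 pi) from the full lognormal density
  sig <- sqrt(log(1 + 0.3^2))
  full <- -dlnorm(100, meanlog = log(150), sdlog = sig, log = TRUE)
  expect_equal(lognormal_nll(100, 150, 0.3),
               full - log(100) - 0.5 * log(2 * pi), tolerance = 1e-12)
  # for a mismatch larger than the error scale, tightening the CV
  # increases the contribution
  expect_gt(lognormal_nll(150, 100, 0.15), lognormal_nll(150, 100, 0.3))
  # minimum over predictions is at pred = obs
  preds <- seq(60, 160, by = 5)
  vals <- vapply(preds, function(p) lognormal_nll(100, p, 0.3), numeric(1))
  expect_equal(preds[which.min(vals)], 100)
  expect_error(lognormal_nll(-1, 1, 0.3), "positive")
  expect_error(lognormal_nll(1, 1, 0), "cv")
})

test_that("multinomial NLL matches hand computations and scales with N", {
  expect_equal(multinomial_nll(rep(0.25, 4), rep(0.25, 4), 1), log(4))
  expect_equal(multinomial_nll(c(1, 0), c(0.8, 0.2), 10), -10 * log(0.8))
  one <- multinomial_nll(c(0.3, 0.7), c(0.5, 0.5), 7)
  expect_equal(multinomial_nll(c(0.3, 0.7), c(0.5, 0.5), 21), 3 * one)
  # predicted zeros are floored, not infinite
  expect_true(is.finite(multinomial_nll(c(0.5, 0.5), c(1, 0), 10)))
  expect_error(multinomial_nll(c(0.5, 0.6), c(0.5, 0.5), 10), "sum to 1")
  expect_error(multinomial_nll(c(0.5, 0.5), c(0.5, 0.5), 0), "effective_n")
})

test_that("recruitment penalties vanish on the deterministic curve", {
  r0 <- 1e6; b0 <- 400; h <- 0.85
  ssb <- rep(b0, 10)
  recruits <- rep(r0, 10)
  lam <- recruitment_penalty(rep(0, 12), log(0.7), recruits, ssb, h,
                             r0, b0, n_pre = 2)
  expect_equal(lam[["lambda2"]], 0)
  expect_equal(lam[["lambda3"]], 0)
  expect_equal(lam[["lambda4"]], 0)
  # residual part of lambda1 (the n log sigma offset remains)
  expect_equal(lam[["lambda1"]], 12 * log(0.7))
  # a single deviation of one sigma contributes 1/2
  lam1 <- recruitment_penalty(0.7, log(0.7), r0, b0, h, r0, b0)
  expect_equal(lam1[["lambda1"]] - log(0.7), 0.5)
  # quadratic scaling
  eps <- c(0.2, -0.1, 0.3)
  a <- recruitment_penalty(eps, log(0.7), recruits[1:3], ssb[1:3], h, r0, b0)
  b <- recruitment_penalty(2 * eps, log(0.7), recruits[1:3], ssb[1:3], h,
                           r0, b0)
  expect_equal(b[["lambda1"]] - 3 * log(0.7),
               4 * (a[["lambda1"]] - 3 * log(0.7)))
  expect_equal(b[["lambda4"]], 4 * a[["lambda4"]])
  expect_error(recruitment_penalty(0, log(0), r0, b0, h, r0, b0), "sigma_R")
})

test_that("fishing-mortality penalties are quadratic and removable", {
  w0 <- penalty_weights(lambda5 = 0, lambda6 = 0)
  expect_equal(unname(f_penalty(c(1, -1), c(2, 2), w0)), c(0, 0))
  w <- penalty_weights(lambda5 = 0.5)
  expect_equal(f_penalty(c(1, -1), c(0.1, 0.1), w)[["lambda5"]], 1)
  expect_equal(f_penalty(c(0, 0), c(1.4, 1.5), w)[["lambda6"]], 0)
  expect_equal(f_penalty(c(0, 0), c(2.5, 1), w)[["lambda6"]], 10)
  expect_error(penalty_weights(lambda5 = -1), ">= 0")
})

test_that("objective breakdown is an accounting identity", {
  sim <- default_sim()
  nll <- total_objective(sim$params, sim$data)
  total <- nll$value[nll$component == "total"]
  expect_equal(total, sum(nll$value[nll$component != "total"]),
               tolerance = 1e-10)
})

test_that("the compiled objective agrees with the R component functions", {
  sim <- default_sim()
  traj <- project(sim$params, sim$data)  # breakdown against the data
  nll <- traj$nll
  years <- sim$data$years
  # survey index components
  for (i in seq_along(sim$data$surveys)) {
    s <- sim$data$surveys[[i]]
    pred <- traj$pred_index[i, match(s$index$year, years)]
    expect_equal(nll$value[nll$component == paste0("index_", s$name)],
                 lognormal_nll(s$index$obs, pred, s$index$cv),
                 tolerance = 1e-10)
  }
  # one composition component
  s <- sim$data$surveys[[3]]
  pred <- traj$pred_scomp[[3]][match(s$comp_years, years), ]
  manual <- sum(vapply(seq_along(s$comp_years), function(i) {
    multinomial_nll(s$comps[i, ], pred[i, ], s$effective_n[i])
  }, numeric(1)))
  expect_equal(nll$value[nll$component == paste0("comp_", s$name)], manual,
               tolerance = 1e-8)
  # penalties
  p <- sim$params
  eps_r <- p$value[p$group == "epsR"]
  eps_f <- p$value[startsWith(p$name, "eps_f_")]
  lam <- recruitment_penalty(eps_r, p$value[p$name == "ln_sigma_R"],
                             traj$by_year$recruits, traj$by_year$ssb,
                             p$value[p$name == "h"], traj$R0, traj$B0,
                             n_pre = 5)
  expect_equal(nll$value[nll$component == "lambda1"], lam[["lambda1"]],
               tolerance = 1e-10)
  expect_equal(nll$value[nll$component == "lambda3"], lam[["lambda3"]],
               tolerance = 1e-10)
  expect_equal(nll$value[nll$component == "lambda4"], lam[["lambda4"]],
               tolerance = 1e-10)
  fl <- f_penalty(eps_f, traj$by_year$f)
  expect_equal(nll$value[nll$component == "lambda5"], fl[["lambda5"]],
               tolerance = 1e-10)
  expect_equal(nll$value[nll$component == "lambda6"], fl[["lambda6"]],
               tolerance = 1e-10)
})

test_that("permuting the surveys leaves the total unchanged", {
  sim <- default_sim()
  total1 <- sum(utils::tail(total_objective(sim$params, sim$data)$value, 1))
  perm <- sim$data
  perm$surveys <- perm$surveys[c(4, 2, 6, 1, 3, 5)]
  p2 <- sim$params
  # catchability/selectivity rows must follow their surveys
  reorder_survey_rows <- function(p, ord) {
    for (s in seq_along(ord)) {
      src <- ord[s]
      p$value[p$name == sprintf("alpha_s%d", s)] <-
        sim$params$value[sim$params$name == sprintf("alpha_s%d", src)]
      p$value[p$name == sprintf("beta_s%d", s)] <-
        sim$params$value[sim$params$name == sprintf("beta_s%d", src)]
      p$value[p$name == sprintf("ln_q_s%d", s)] <-
        sim$params$value[sim$params$name == sprintf("ln_q_s%d", src)]
    }
    p
  }
  p2 <- reorder_survey_rows(p2, c(4, 2, 6, 1, 3, 5))
  total2 <- sum(utils::tail(total_objective(p2, perm)$value, 1))
  expect_equal(total1, total2, tolerance = 1e-10)
})

test_that("error-free pseudo-data put every data component at its minimum", {
  sim <- default_sim()
  fit <- default_cfgI_fit()
  pseudo <- generate_pseudodata(fit)
  nll <- total_objective(fit$params, pseudo, fit$config)
  years <- sim$data$years
  # composition minima are the observed entropies
  for (i in seq_along(pseudo$surveys)) {
    s <- pseudo$surveys[[i]]
    if (length(s$comp_years) == 0) next
    entropy <- -sum(s$effective_n *
                      rowSums(ifelse(s$comps > 0,
                                     s$comps * log(s$comps), 0)))
    expect_equal(nll$value[nll$component == paste0("comp_", s$name)],
                 entropy, tolerance = 1e-8)
  }
  # index and catch residuals are exactly zero
  for (i in seq_along(pseudo$surveys)) {
    s <- pseudo$surveys[[i]]
    expect_equal(nll$value[nll$component == paste0("index_", s$name)],
                 sum(0.5 * log(log(1 + s$index$cv^2))), tolerance = 1e-8)
  }
  sigC <- fit$params$value[fit$params$name == "sigma_C"]
  expect_equal(nll$value[nll$component == "catch"],
               41 * 0.5 * log(log(1 + sigC^2)), tolerance = 1e-8)
})
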