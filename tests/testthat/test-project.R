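test_that("unfished parameters give a stationary population at B0", {
  sim <- default_sim()
  cfg <- configuration(bias_correct = FALSE)
  p <- default_parameters()
  p <- set_parameters(p, mu_f = -30)  # F effectively zero
  traj <- project(p, sim$data, cfg)
  expect_equal(traj$by_year$ssb, rep(traj$B0, length(sim$data$years)),
               tolerance = 1e-9)
  expect_equal(traj$by_year$recruits, rep(traj$R0, 41), tolerance = 1e-12)
})

test_that("three-age dynamics match an independent R implementation", {
  years <- 2000:2004
  data <- toy_bundle(years, n_ages = 3)
  eps <- c(0.3, 0.1, -0.2, 0.4, 0, 0.25)
  p <- toy_params(years, 3, ln_M = log(0.8), mu_f = log(0.1),
                  eps_R = eps)
  cfg <- configuration(bias_correct = FALSE)
  traj <- project(p, data, cfg)

  # brute-force oracle: explicit year loop over the Baranov equations
  M <- 0.8; F <- 0.1
  sel <- 1 / (1 + exp(-((1:3) - 1.3) / 2.8))
  linf <- exp(4.11); k <- exp(-0.799)
  w <- 1e-9 * (linf * (1 - exp(-k * (1:3))))^3
  R <- exp(16 + eps[-1])
  N <- matrix(0, 5, 3)
  N[1, ] <- c(R[1], exp(16 + eps[1]) * exp(-M),
              exp(16) * exp(-2 * M) / (1 - exp(-M)))
  Z <- outer(rep(1, 5), M + sel * F)
  C <- matrix(0, 5, 3)
  for (t in 1:5) {
    C[t, ] <- sel * F / Z[t, ] * (1 - exp(-Z[t, ])) * N[t, ]
    if (t < 5) {
      N[t + 1, 1] <- R[t + 1]
      N[t + 1, 2] <- N[t, 1] * exp(-Z[t, 1])
      N[t + 1, 3] <- N[t, 2] * exp(-Z[t, 2]) + N[t, 3] * exp(-Z[t, 3])
    }
  }
  expect_equal(traj$N, N, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(traj$catch_at_age, C, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(traj$by_year$catch_pred, as.numeric(C %*% w),
               tolerance = 1e-10)
  expect_equal(traj$by_year$ssb, as.numeric(N[, 3] * w[3]),
               tolerance = 1e-10)
})

test_that("single-age survival is one exponential decay step", {
  years <- 2000:2003
  nb <- 30L
  data <- data_bundle(
    surveys = list(list(name = "s",
                        index = tibble::tibble(year = 2001, obs = 1,
                                               cv = 0.3),
                        comp_years = integer(), comps = NULL,
                        effective_n = numeric())),
    fishery = list(catch = tibble::tibble(year = years, obs = 1),
                   comp_years = integer(), comps = NULL,
                   effective_n = numeric()),
    years = years, n_ages = 1, maturity_age = 1)
  p <- toy_params(years, 1, ln_M = log(0.5), mu_f = log(0.2))
  traj <- project(p, data, configuration(bias_correct = FALSE))
  surv <- traj$N[2, 1] - traj$by_year$recruits[2]
  expect_equal(surv, traj$N[1, 1] * exp(-traj$Z[1, 1]), tolerance = 1e-12)
  expect_equal(traj$Z[1, 1],
               0.5 + 0.2 / (1 + exp(-(1 - 1.3) / 2.8)), tolerance = 1e-12)
})

test_that("numbers are conserved between survival, natural death and catch", {
  traj <- default_sim()$trajectory
  A <- ncol(traj$N); Y <- nrow(traj$N)
  M <- exp(default_sim()$params$value[default_sim()$params$name == "ln_M"])
  for (t in seq_len(Y - 1)) {
    for (a in seq_len(A - 2)) {
      z <- traj$Z[t, a]
      deaths <- traj$N[t, a] * (1 - exp(-z))
      natural <- deaths * M / z
      catch <- traj$catch_at_age[t, a]
      expect_equal(traj$N[t + 1, a + 1] + natural + catch, traj$N[t, a],
                   tolerance = 1e-9)
    }
  }
})

test_that("predicted compositions are simplexes and projection is deterministic", {
  sim <- default_sim()
  traj <- sim$trajectory
  for (s in seq_along(traj$pred_scomp)) {
    expect_equal(rowSums(traj$pred_scomp[[s]]), rep(1, nrow(traj$N)),
                 tolerance = 1e-9)
  }
  expect_equal(rowSums(traj$pred_fcomp), rep(1, nrow(traj$N)),
               tolerance = 1e-9)
  again <- project(sim$params, sim$data)
  expect_identical(traj$N, again$N)
  expect_identical(traj$by_year, again$by_year)
})

test_that("non-finite population states are reported as failures", {
  sim <- default_sim()
  p <- set_parameters(default_parameters(), ln_Rbar = 800)
  expect_error(project(p, sim$data), "projection failed")
})
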