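test_that("the default scenario reproduces the data census", {
  scn <- scenario()
  idx_years <- sum(lengths(purrr::map(scn$design, "index_years")))
  cmp_years <- sum(lengths(purrr::map(scn$design, "comp_years")))
  expect_equal(cmp_years, 35)
  expect_equal(idx_years, 54)
  expect_equal(length(scn$catch_years), 41)
  expect_equal(length(scn$fishery_comp_years), 13)
  expect_equal(sample_size(default_sim()$data), 143L)
})

test_that("truth simulation is seeded and distributionally correct", {
  scn <- scenario()
  t1 <- simulate_truth(scn, seed = 3)
  t2 <- simulate_truth(scn, seed = 3)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$trajectory$N, t2$trajectory$N)
  # pool draws across seeds: about 1,000 recruitment deviations
  eps <- unlist(lapply(1:22, function(s) {
    p <- simulate_truth(scn, seed = s)$params
    p$value[p$group == "epsR"]
  }))
  n <- length(eps)
  expect_gte(n, 1000)
  se_mean <- 0.7 / sqrt(n)
  expect_lt(abs(mean(eps)), 3 * se_mean)
  se_sd <- 0.7 / sqrt(2 * n)
  expect_lt(abs(sd(eps) - 0.7), 3 * se_sd)
  # deterministic variant: no deviations, recruitment at the mean
  p0 <- set_parameters(scn$params, eps_R = rep(0, 46),
                       eps_f = rep(0, 41))
  traj <- project(p0, krillphase:::empty_bundle(scn),
                  configuration(bias_correct = FALSE))
  expect_equal(length(unique(round(traj$by_year$recruits, 6))), 1)
})

test_that("observation noise has the nominal structure", {
  scn <- scenario()
  truth <- simulate_truth(scn, seed = 3)
  # noise off reproduces the predictions exactly (and matches pseudo-data)
  scn_quiet <- scenario(noise = FALSE)
  quiet <- simulate_observations(truth, scn_quiet, seed = 5)
  pos <- match(quiet$surveys[[3]]$index$year, scn$years)
  expect_equal(quiet$surveys[[3]]$index$obs,
               as.numeric(truth$trajectory$pred_index[3, pos]),
               tolerance = 1e-12)
  expect_equal(rowSums(quiet$surveys[[3]]$comps),
               rep(1, length(quiet$surveys[[3]]$comp_years)))
  # noisy compositions still lie on the simplex
  noisy <- simulate_observations(truth, scn, seed = 5)
  for (s in noisy$surveys) {
    if (length(s$comp_years) > 0) {
      expect_equal(rowSums(s$comps), rep(1, length(s$comp_years)),
                   tolerance = 1e-9)
    }
  }
  # Monte-Carlo check of the index CV (survey 3, first design year)
  draws <- vapply(1:400, function(i) {
    simulate_observations(truth, scn, seed = 1000 + i)$surveys[[3]]$index$obs[1]
  }, numeric(1))
  cv_hat <- sd(draws) / mean(draws)
  expect_lt(abs(cv_hat - 0.4) / 0.4, 0.10)
})

test_that("natural mortality is recovered within its asymptotic interval", {
  # scaled-down recovery study: configuration II (recruitment + M) refitted
  # to noisy synthetic bundles; the true ln M should fall inside the 95%
  # interval in most replicates. The truth holds F at its flat default so
  # the estimating model (which does not estimate F) is correctly
  # specified; otherwise M absorbs the fishing-mortality misspecification.
  cfg <- preset_configuration("II")
  scn <- scenario(f_ramp = c(0, 0), f_sd = 0)
  hits <- 0L
  n_rep <- 6L
  for (s in seq_len(n_rep)) {
    sim <- simulate_bundle(scn, seed = 100 + s)
    fit <- phased_minimize(cfg, sim$data,
                           assign_random_phases(cfg, seed = s))
    if (!fit$pd_hessian) next
    ai <- asymptotic_intervals(fit)
    row <- ai[ai$quantity == "ln_M", ]
    truth <- sim$params$value[sim$params$name == "ln_M"]
    hits <- hits + (row$lower <= truth && truth <= row$upper)
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("bundles survive a write/read round trip", {
  sim <- default_sim()
  dir <- withr::local_tempdir()
  write_bundle(sim$data, dir)
  back <- read_bundle(dir)
  expect_equal(back$years, sim$data$years)
  expect_equal(back$length_bins, sim$data$length_bins)
  for (i in seq_along(sim$data$surveys)) {
    expect_equal(back$surveys[[i]]$index, sim$data$surveys[[i]]$index)
    expect_equal(back$surveys[[i]]$comps, sim$data$surveys[[i]]$comps,
                 tolerance = 1e-12)
  }
  expect_equal(back$fishery$catch, sim$data$fishery$catch)
  expect_equal(sample_size(back), 143L)
})
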