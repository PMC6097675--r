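# shared fixtures, built in code at test time

# default synthetic bundle (memoised per session: simulation is cheap, fits
# that use it are not)
default_sim <- local({
  cache <- NULL
  function(seed = 7L) {
    if (is.null(cache)) {
      cache <<- simulate_bundle(scenario(), seed = seed)
    }
    cache
  }
})

# minimal bundle on a 3-age grid for hand-checkable dynamics
toy_bundle <- function(years = 2000:2004, n_ages = 3) {
  nb <- 30L
  surveys <- list(list(
    name = "trawl",
    index = tibble::tibble(year = years[2], obs = 1, cv = 0.3),
    comp_years = years[2],
    comps = matrix(1 / nb, 1, nb),
    effective_n = 50))
  fishery <- list(catch = tibble::tibble(year = years, obs = 1),
                  comp_years = integer(),
                  comps = NULL, effective_n = numeric())
  data_bundle(surveys, fishery, years = years, n_ages = n_ages)
}

toy_params <- function(years = 2000:2004, n_ages = 3, ...) {
  set_parameters(default_parameters(years, n_ages, n_surveys = 1), ...)
}

# one quick converged cfgI fit on the default bundle (memoised)
default_cfgI_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- preset_configuration("I")
      cache <<- phased_minimize(cfg, default_sim()$data,
                                assign_random_phases(cfg, seed = 11))
    }
    cache
  }
})
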