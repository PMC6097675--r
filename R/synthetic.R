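#' Synthetic observation scenario
#'
#' Defines a fully synthetic krill-like study: true parameter values, the
#' survey/fishery observation design, and noise switches. The default
#' design emulates the Subarea 48.1 data census: six survey series
#' (summer/winter acoustic, summer/winter IKMT, summer/winter RMT8)
#' contributing 54 index years and 35 composition years in total, 41
#' fishery catch years (1976-2016) and 13 fishery composition years, so
#' the comparison-table sample size is 143. Acoustic series carry indices
#' only; trawl series carry indices and length compositions. Index and
#' catch errors are lognormal; composition errors are multinomial at the
#' effective sample size.
#'
#' @param params True parameter table; defaults to the pre-specified
#'   initial values (so estimation starts correctly specified apart from
#'   the drawn deviations).
#' @param years Model years.
#' @param index_cv_acoustic,index_cv_trawl Survey index CVs (not published
#'   for the real surveys; defaults 0.3 and 0.4).
#' @param effective_n_survey,effective_n_fishery Multinomial effective
#'   sample sizes for compositions.
#' @param noise Observation noise on (`TRUE`) or off (`FALSE`). With noise
#'   off, [observe()] returns the model predictions exactly.
#' @param f_ramp Range of the linear trend in log-F deviations over the
#'   catch years (the fishery ramps up).
#' @param f_sd SD of the annual log-F deviation noise around the ramp.
#' @param rng_seed Seed used by [simulate_truth()] and [observe()].
#' @return An object of class `krill_scenario`.
#' @export
scenario <- function(params = default_parameters(years),
                     years = 1976:2016,
                     index_cv_acoustic = 0.3, index_cv_trawl = 0.4,
                     effective_n_survey = 200, effective_n_fishery = 500,
                     noise = TRUE, f_ramp = c(-1.5, 1.5), f_sd = 0.2,
                     rng_seed = 1L) {
  design <- list(
    list(name = "acoustic_summer", type = "acoustic",
         index_years = 1992:2004, comp_years = integer()),
    list(name = "acoustic_winter", type = "acoustic",
         index_years = 2005:2010, comp_years = integer()),
    list(name = "ikmt_summer", type = "trawl",
         index_years = 1991:2002, comp_years = 1991:2002),
    list(name = "ikmt_winter", type = "trawl",
         index_years = 2003:2008, comp_years = 2003:2008),
    list(name = "rmt8_summer", type = "trawl",
         index_years = 1982:1990, comp_years = 1982:1990),
    list(name = "rmt8_winter", type = "trawl",
         index_years = 2009:2016, comp_years = 2009:2016))
  structure(list(params = params, years = as.integer(years),
                 design = design,
                 catch_years = as.integer(years),
                 fishery_comp_years = 2003:2015,
                 index_cv_acoustic = index_cv_acoustic,
                 index_cv_trawl = index_cv_trawl,
                 effective_n_survey = effective_n_survey,
                 effective_n_fishery = effective_n_fishery,
                 noise = isTRUE(noise),
                 f_ramp = f_ramp, f_sd = f_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "krill_scenario")
}

#' Draw a true parameter set and its trajectory
#'
#' Draws annual recruitment deviations from N(0, sigma_R^2) (lognormal
#' recruitment around the mean) and log-F deviations as a linear ramp plus
#' noise (a fishery building up over the catch years), then projects the
#' deterministic population dynamics at those true values.
#'
#' @param scn A scenario, see [scenario()].
#' @param seed Overrides the scenario seed.
#' @return A list with elements `params` (true parameter table) and
#'   `trajectory` (a `krill_trajectory`).
#' @export
simulate_truth <- function(scn, seed = scn$rng_seed) {
  stopifnot(inherits(scn, "krill_scenario"))
  params <- scn$params
  set.seed(seed)
  sig_r <- exp(params$value[params$name == "ln_sigma_R"])
  n_eps <- sum(params$group == "epsR")
  eps_r <- stats::rnorm(n_eps, 0, sig_r)
  ny <- length(scn$years)
  ramp <- seq(scn$f_ramp[1], scn$f_ramp[2], length.out = ny)
  eps_f <- ramp + stats::rnorm(ny, 0, scn$f_sd)
  params <- set_parameters(params, eps_R = eps_r, eps_f = eps_f)
  template <- empty_bundle(scn)
  list(params = params,
       trajectory = project(params, template))
}

# bundle with the scenario design but placeholder observations (used as a
# template for prediction-based filling)
empty_bundle <- function(scn) {
  nb <- 30L
  edges <- seq(10, 70, by = 2)
  surveys <- purrr::map(scn$design, function(d) {
    cv <- if (d$type == "acoustic") scn$index_cv_acoustic else scn$index_cv_trawl
    list(name = d$name,
         index = tibble::tibble(year = d$index_years, obs = 1,
                                cv = cv),
         comp_years = d$comp_years,
         comps = matrix(1 / nb, length(d$comp_years), nb),
         effective_n = rep(scn$effective_n_survey, length(d$comp_years)))
  })
  fishery <- list(catch = tibble::tibble(year = scn$catch_years, obs = 1),
                  comp_years = scn$fishery_comp_years,
                  comps = matrix(1 / nb, length(scn$fishery_comp_years), nb),
                  effective_n = rep(scn$effective_n_fishery,
                                    length(scn$fishery_comp_years)))
  data_bundle(surveys, fishery, years = scn$years, length_bins = edges)
}

#' Generate observations from a trajectory
#'
#' Fills the scenario's observation design with values generated from the
#' model predictions: indices and catches with multiplicative lognormal
#' error at the nominal CV (mean-unbiased), and length compositions as
#' multinomial draws at the effective sample size. With the scenario's
#' noise switch off the observations equal the predictions exactly.
#'
#' @param truth Output of [simulate_truth()] (or any list with a
#'   `trajectory` and `params`).
#' @param scn The scenario.
#' @param seed Overrides the scenario seed for the observation noise.
#' @return A `krill_data` bundle.
#' @export
simulate_observations <- function(truth, scn, seed = scn$rng_seed + 1L) {
  stopifnot(inherits(scn, "krill_scenario"))
  traj <- truth$trajectory
  template <- empty_bundle(scn)
  set.seed(seed)
  sigma_c <- truth$params$value[truth$params$name == "sigma_C"]
  fill_bundle(template, traj, noise = scn$noise, sigma_c = sigma_c)
}

# replace observations in a bundle template by model predictions, with or
# without observation noise
fill_bundle <- function(template, traj, noise = FALSE, sigma_c = 0.1) {
  years <- template$years
  draw_logn <- function(pred, cv) {
    if (!noise) return(pred)
    sig <- sqrt(log(1 + cv^2))
    pred * exp(stats::rnorm(length(pred), -sig^2 / 2, sig))
  }
  draw_comp <- function(pred_rows, neff) {
    if (!noise) return(pred_rows)
    out <- pred_rows
    for (i in seq_len(nrow(pred_rows))) {
      n <- max(1L, round(neff[i]))
      out[i, ] <- as.numeric(stats::rmultinom(1, n, pmax(pred_rows[i, ],
                                                         1e-12))) / n
    }
    out
  }
  for (s in seq_along(template$surveys)) {
    sv <- template$surveys[[s]]
    pos <- match(sv$index$year, years)
    sv$index$obs <- draw_logn(as.numeric(traj$pred_index[s, pos]),
                              sv$index$cv)
    if (length(sv$comp_years) > 0) {
      cpos <- match(sv$comp_years, years)
      sv$comps <- draw_comp(traj$pred_scomp[[s]][cpos, , drop = FALSE],
                            sv$effective_n)
    }
    template$surveys[[s]] <- sv
  }
  cpos <- match(template$fishery$catch$year, years)
  template$fishery$catch$obs <- draw_logn(traj$by_year$catch_pred[cpos],
                                          sigma_c)
  if (length(template$fishery$comp_years) > 0) {
    fpos <- match(template$fishery$comp_years, years)
    template$fishery$comps <- draw_comp(
      traj$pred_fcomp[fpos, , drop = FALSE], template$fishery$effective_n)
  }
  validate_bundle(template)
}

#' One-call synthetic bundle
#'
#' Convenience wrapper: draw a truth and observe it.
#'
#' @inheritParams simulate_truth
#' @return List with `params`, `trajectory`, `data`.
#' @export
simulate_bundle <- function(scn = scenario(), seed = scn$rng_seed) {
  truth <- simulate_truth(scn, seed = seed)
  data <- simulate_observations(truth, scn, seed = seed + 1L)
  c(truth, list(data = data))
}
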