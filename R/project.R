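# Flat problem description handed to the compiled core. Year positions are
# 0-based offsets into the model year vector.
build_problem <- function(data, config = configuration()) {
  stopifnot(inherits(data, "krill_data"))
  years <- data$years
  nb <- length(data$length_bins) - 1L
  series <- function(s) {
    list(idx_pos = as.integer(match(s$index$year, years) - 1L),
         idx_obs = as.numeric(s$index$obs),
         idx_sig2 = log(1 + s$index$cv^2),
         cmp_pos = as.integer(match(s$comp_years, years) - 1L),
         cmp_obs = matrix(as.numeric(s$comps), nrow = length(s$comp_years),
                          ncol = nb),
         cmp_neff = as.numeric(s$effective_n))
  }
  list(n_ages = data$n_ages,
       n_years = length(years),
       n_pre = max(data$n_ages - 2L, 0L),
       n_surveys = length(data$surveys),
       f_start = 0L,
       maturity = as.numeric(seq_len(data$n_ages) >= data$maturity_age),
       weight_a = data$weight_a, weight_b = data$weight_b,
       edges = as.numeric(data$length_bins),
       surveys = purrr::map(data$surveys, series),
       catch_pos = as.integer(match(data$fishery$catch$year, years) - 1L),
       catch_obs = as.numeric(data$fishery$catch$obs),
       fishery_comp = series(list(index = tibble::tibble(year = integer(),
                                                         obs = numeric(),
                                                         cv = numeric()),
                                  comp_years = data$fishery$comp_years,
                                  comps = data$fishery$comps,
                                  effective_n = data$fishery$effective_n)),
       weights = config$penalty_weights,
       bias_correct = config$bias_correct)
}

#' Project the population and predicted observations
#'
#' Runs the deterministic age-structured dynamics for a parameter set:
#' initial age structure seeded from mean recruitment and the pre-data
#' recruitment deviations, annual survival under competing natural and
#' fishing mortality (Baranov catch equation), spawning biomass with
#' knife-edge maturity, and the predicted survey indices, length
#' compositions (through the age-length transition), and fishery catches.
#'
#' @param params Parameter table, see [default_parameters()].
#' @param data A `krill_data` bundle (supplies the model grid and the
#'   observation design).
#' @param config Configuration (supplies penalty weights and the
#'   bias-correction switch; the estimation policy is not used here).
#' @return An object of class `krill_trajectory`: a list with a `by_year`
#'   tibble (`year`, `recruits`, `ssb`, `f`, `catch_pred`), matrices `N`,
#'   `Z`, `catch_at_age` (year x age), survey predictions, the
#'   age-length matrix, `B0`, and the objective breakdown at these
#'   parameters.
#' @export
project <- function(params, data, config = configuration()) {
  pb <- build_problem(data, config)
  par <- par_vector(params)
  rep <- krill_eval_cpp(par, pb)
  if (!isTRUE(rep$ok)) {
    stop("population projection failed: non-finite or negative state")
  }
  as_trajectory(rep, data)
}

as_trajectory <- function(rep, data) {
  years <- data$years
  structure(list(
    by_year = tibble::tibble(year = years,
                             recruits = as.numeric(rep$R),
                             ssb = as.numeric(rep$SSB),
                             f = as.numeric(rep$F),
                             catch_pred = as.numeric(rep$catch_pred)),
    N = rep$N, Z = rep$Z, catch_at_age = rep$catch_at_age,
    pred_index = rep$pred_index, pred_scomp = rep$pred_scomp,
    pred_fcomp = rep$pred_fcomp,
    age_length = rep$age_length, weight_at_age = rep$weight_at_age,
    sel_f = rep$sel_f, sel_s = rep$sel_s,
    B0 = rep$B0, R0 = rep$R0, phi0 = rep$phi0,
    nll = nll_breakdown_from_report(rep, data),
    years = years),
    class = "krill_trajectory")
}

#' @export
print.krill_trajectory <- function(x, ...) {
  cat("<krill_trajectory> ", length(x$years), " years, ",
      ncol(x$N), " ages\n", sep = "")
  cat("  B0 = ", format(x$B0, digits = 4), " t, final SSB = ",
      format(utils::tail(x$by_year$ssb, 1), digits = 4), " t\n", sep = "")
  cat("  objective total = ", format(sum(x$nll$value), digits = 8),
      "\n", sep = "")
  invisible(x)
}

nll_breakdown_from_report <- function(rep, data) {
  ns <- length(data$surveys)
  nm <- purrr::map_chr(seq_len(ns), function(i) {
    data$surveys[[i]]$name %||% paste0("survey_", i)
  })
  tibble::tibble(
    component = c(paste0("index_", nm), paste0("comp_", nm),
                  "comp_fishery", "catch",
                  paste0("lambda", 1:6), "total"),
    type = c(rep("index", ns), rep("composition", ns), "composition",
             "catch", rep("penalty", 6), "total"),
    value = c(as.numeric(rep$nll_index), as.numeric(rep$nll_scomp),
              rep$nll_fcomp, rep$nll_catch, as.numeric(rep$penalties),
              rep$total))
}

#' Penalized negative log-likelihood with its breakdown
#'
#' Evaluates the full objective for a parameter set on a data bundle:
#' lognormal index and catch components, multinomial composition
#' components, and the recruitment (lambda1-4) and fishing-mortality
#' (lambda5-6) penalties. The `total` row equals the sum of all
#' components.
#'
#' @inheritParams project
#' @return A tibble with columns `component`, `type`, `value`; the last row
#'   is the total.
#' @export
total_objective <- function(params, data, config = configuration()) {
  traj <- project(params, data, config)
  traj$nll
}

#' Tidy a projected trajectory
#'
#' @param x A `krill_trajectory`.
#' @param ... Unused.
#' @return The `by_year` tibble in long form (`year`, `quantity`, `value`).
#' @export
tidy.krill_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$by_year, -"year", names_to = "quantity",
                      values_to = "value")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
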