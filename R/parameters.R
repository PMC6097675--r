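#' Default parameter table for the krill assessment
#'
#' Builds the full table of potentially estimable quantities of the
#' integrated krill assessment: recruitment scale and deviations, natural
#' mortality, logistic selectivity location/spread for six surveys and the
#' fishery, mean fishing mortality and annual deviations, observation-model
#' quantities (catch CV, catchabilities), steepness, and von Bertalanffy
#' growth. Each row carries the pre-specified initial value, bounds (where
#' the quantity is bounded), the smooth transform used during estimation,
#' and the parameter group it belongs to. With the default dimensions
#' (ages 1-7, model years 1976-2016, six surveys) the table has 118 rows:
#' 46 recruitment deviations (the five pre-data years 1971-1975 seed the
#' initial age structure), 41 fishing-mortality deviations, 14 selectivity
#' parameters, and 17 scalars.
#'
#' @param years Integer vector of model (calendar) years. Default 1976:2016.
#' @param n_ages Number of age classes; the oldest is a plus group. Default 7.
#' @param n_surveys Number of survey series. Default 6.
#' @return A tibble with columns `name`, `group`, `value`, `lower`, `upper`,
#'   `transform` ("identity", "logit" or "log"), `year`, `survey`.
#' @export
#' @examples
#' p <- default_parameters()
#' nrow(p) # 118
default_parameters <- function(years = 1976:2016, n_ages = 7, n_surveys = 6) {
  n_pre <- max(n_ages - 2L, 0L)
  rec_years <- c(seq(min(years) - n_pre, length.out = n_pre), years)
  row <- function(name, group, value, lower = NA_real_, upper = NA_real_,
                  transform = "identity", year = NA_integer_,
                  survey = NA_integer_) {
    tibble::tibble(name = name, group = group, value = value, lower = lower,
                   upper = upper, transform = transform,
                   year = as.integer(year), survey = as.integer(survey))
  }
  sel_alpha <- c(3.3, rep(1.3, n_surveys - 1L))  # survey 1: summer acoustic
  sel_beta  <- c(0.06, rep(2.8, n_surveys - 1L))
  sel_rows <- purrr::map_dfr(seq_len(n_surveys), function(s) {
    dplyr::bind_rows(
      row(sprintf("alpha_s%d", s), "ssel", sel_alpha[s], survey = s),
      row(sprintf("beta_s%d", s), "ssel", sel_beta[s], transform = "log",
          survey = s))
  })
  dplyr::bind_rows(
    row("ln_R0", "R0", 16.0),
    row("ln_Rbar", "Rbar", 16.0),
    row(sprintf("eps_R_%d", rec_years), "epsR", 0, -15, 15, "logit",
        year = rec_years),
    row("ln_sigma_R", "sigmaR", -0.3567),
    row("ln_M", "M", -0.2232, -5, 5, "logit"),
    sel_rows,
    row("alpha_f", "fsel", 1.3),
    row("beta_f", "fsel", 2.8, transform = "log"),
    row("mu_f", "F", -2.3026),
    row(sprintf("eps_f_%d", years), "F", 0, -12, 8, "logit", year = years),
    row("sigma_C", "sigmaC", 0.1, transform = "log"),
    row("ln_q_f", "qf", 0),
    row("h", "h", 0.85, 0.21, 1, "logit"),
    row(sprintf("ln_q_s%d", seq_len(n_surveys)), "qs", 0,
        survey = seq_len(n_surveys)),
    row("ln_Linf", "growth", 4.11, 2.5, 5, "logit"),
    row("ln_k", "growth", -0.799, -10, 5, "logit"),
    row("ln_sigma_v", "growth", 1.459, 0.2, 5, "logit")
  )
}

#' Parameter group labels
#'
#' The twelve groups that configurations switch on for estimation, in the
#' order used by the configuration grid, plus the never-estimated catch-CV
#' group `"sigmaC"`. A group is activated or fixed as a block; the
#' fishing-mortality group `"F"` contains the mean log-F plus all annual
#' deviations.
#'
#' @param include_fixed Include the never-estimated `"sigmaC"` group.
#' @return Character vector of group labels.
#' @export
parameter_groups <- function(include_fixed = FALSE) {
  g <- c("R0", "Rbar", "epsR", "F", "M", "fsel", "ssel",
         "qf", "sigmaR", "h", "qs", "growth")
  if (include_fixed) c(g, "sigmaC") else g
}

#' Count the parameters a configuration estimates
#'
#' Sums group sizes over the configuration's estimated groups. Survey
#' selectivity counts two parameters (location, spread) per survey listed in
#' the configuration's `ssel_surveys`; the fishing-mortality group counts
#' the mean plus every annual deviation.
#'
#' @param config A configuration, see [configuration()].
#' @param params Parameter table; defaults to [default_parameters()].
#' @return Integer count of estimated parameters.
#' @export
#' @examples
#' count_parameters(preset_configuration("I"))   # 48
#' count_parameters(preset_configuration("XVI")) # 96
count_parameters <- function(config, params = default_parameters()) {
  stopifnot(inherits(config, "krill_config"))
  unknown <- setdiff(config$estimated_groups, parameter_groups(TRUE))
  if (length(unknown) > 0) {
    stop("unknown parameter group(s): ", paste(unknown, collapse = ", "))
  }
  idx <- estimated_index(config, params)
  length(idx)
}

#' Row indices of the parameters a configuration estimates
#' @noRd
estimated_index <- function(config, params) {
  est <- params$group %in% config$estimated_groups
  if ("ssel" %in% config$estimated_groups) {
    est[params$group == "ssel" &
          !(params$survey %in% config$ssel_surveys)] <- FALSE
  }
  which(est)
}

#' Set parameter values by name
#'
#' @param params Parameter table.
#' @param ... Named values, e.g. `ln_M = -0.1`. Vectors are matched against
#'   name prefixes for year-indexed parameters (`eps_R`, `eps_f`).
#' @return The modified parameter table.
#' @export
set_parameters <- function(params, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) == 1 && nm %in% params$name) {
      params$value[params$name == nm] <- v
    } else {
      pref <- params$name[startsWith(params$name, paste0(nm, "_"))]
      if (length(pref) != length(v)) {
        stop("cannot match ", length(v), " values to parameter '", nm, "'")
      }
      params$value[params$name %in% pref] <- v
    }
  }
  params
}

# canonical parameter vector order is the row order of default_parameters();
# C++ slices it by the dimensions carried in the problem list
par_vector <- function(params) {
  stats::setNames(params$value, params$name)
}
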