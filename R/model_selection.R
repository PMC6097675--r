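#' Akaike and Bayesian information criteria
#'
#' `AIC = 2*nll + 2*k` and `BIC = 2*nll + log(n)*k`, where `nll` is the
#' negative log-likelihood at the optimum, `k` the number of estimated
#' parameters and `n` the sample size (for these assessments, the total
#' number of data-years across surveys and the fishery, see
#' [sample_size()]).
#'
#' @param nll Negative log-likelihood (may be a vector).
#' @param k Number of estimated parameters.
#' @param n Sample size (needed for BIC).
#' @return A tibble with columns `aic` and `bic`.
#' @export
information_criteria <- function(nll, k, n) {
  stopifnot(all(k >= 0), n >= 1)
  tibble::tibble(aic = 2 * nll + 2 * k, bic = 2 * nll + log(n) * k)
}

round_half_up <- function(x) floor(x + 0.5)

#' Delta-AIC / delta-BIC comparison table
#'
#' Computes AIC and BIC for each candidate configuration and their
#' differences from the minimum-criterion configuration. Deltas are
#' computed on the unrounded criteria and then rounded half-up to integers
#' for display, matching how assessment comparison tables are printed.
#'
#' @param rows A data frame with columns `name`, `nll`, `k` (one row per
#'   configuration).
#' @param n Sample size for the BIC.
#' @return A tibble with `name`, `nll`, `k`, `aic`, `bic`, `delta_aic`,
#'   `delta_bic` (the deltas rounded to integers).
#' @export
#' @examples
#' delta_table(data.frame(name = c("A", "B"), nll = c(100, 90),
#'                        k = c(5, 10)), n = 143)
delta_table <- function(rows, n) {
  rows <- tibble::as_tibble(rows)
  stopifnot(nrow(rows) > 0, all(c("name", "nll", "k") %in% names(rows)))
  if (anyDuplicated(rows$name)) stop("duplicate configuration names")
  ic <- information_criteria(rows$nll, rows$k, n)
  dplyr::mutate(rows,
                aic = ic$aic, bic = ic$bic,
                delta_aic = round_half_up(.data$aic - min(.data$aic)),
                delta_bic = round_half_up(.data$bic - min(.data$bic)))
}

#' Sample size of a data bundle
#'
#' The BIC sample size used for these assessments: the number of
#' survey-composition years plus survey-index years plus fishery catch
#' years plus fishery-composition years. The Subarea 48.1 census
#' (35 + 54 + 41 + 13) gives 143.
#'
#' @param data A data bundle, see [data_bundle()].
#' @return Integer count of data-years.
#' @export
sample_size <- function(data) {
  stopifnot(inherits(data, "krill_data"))
  n_idx <- sum(vapply(data$surveys, function(s) nrow(s$index), integer(1)))
  n_cmp <- sum(vapply(data$surveys, function(s) length(s$comp_years),
                      integer(1)))
  n_idx + n_cmp + nrow(data$fishery$catch) + length(data$fishery$comp_years)
}

#' Annual mortality fraction from an instantaneous rate
#'
#' Converts an instantaneous mortality rate M (per year) to the percentage
#' of individuals dying within a year, `100 * (1 - exp(-M))`, rounded to
#' the nearest integer percent for display (e.g. M = 0.8 is 55% annual
#' mortality).
#'
#' @param M Instantaneous mortality rate(s), per year.
#' @param digits Rounding for display; `NULL` returns the unrounded value.
#' @return Percentage(s) dying per year.
#' @export
annual_mortality_fraction <- function(M, digits = 0) {
  stopifnot(all(M >= 0))
  pct <- 100 * (1 - exp(-M))
  if (is.null(digits)) pct else round_half_up(pct * 10^digits) / 10^digits
}

#' Number of ordered phase assignments
#'
#' The count of distinct ordered assignments reported for scattering
#' `n_groups` parameter groups into `n_phases` activation phases, computed
#' as `n_groups! * (n_groups - n_phases)!` (12 groups in 7 phases gives
#' about 5.7e10). This product form matches the published expression for
#' the krill configuration grid; note it differs from the falling-factorial
#' count `n_groups! / (n_groups - n_phases)!`.
#'
#' @param n_groups Number of parameter groups.
#' @param n_phases Number of phases.
#' @return A double (the counts overflow integers).
#' @export
phase_ordering_count <- function(n_groups, n_phases) {
  stopifnot(n_groups >= n_phases, n_phases >= 1)
  factorial(n_groups) * factorial(n_groups - n_phases)
}

#' Published benchmark summary for the Subarea 48.1 configurations
#'
#' The published per-configuration summary of the Subarea 48.1 krill
#' assessment (22 configurations): estimated parameter counts, median phase
#' reorderings, percentage of replicates at the best objective, lowest
#' negative log-likelihood, maximum gradient, delta-AIC/BIC and whether the
#' configuration passed the MCMC convergence diagnostics. Used as numeric
#' input when checking the comparison-table arithmetic; the absolute
#' likelihoods are properties of the (undeposited) survey and fishery data.
#'
#' @return A tibble with one row per configuration.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "krill48_1_reference.csv",
                      package = "krillphase")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    cfg = readr::col_character(),
                    coda_pass = readr::col_logical(),
                    .default = readr::col_double()))
}
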