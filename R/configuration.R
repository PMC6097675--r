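#' Create an assessment configuration
#'
#' A configuration names the parameter groups that are estimated (all other
#' quantities stay at their pre-specified initial values), the replicate and
#' phase policy for the randomized-phase estimation, and the penalty
#' weights of the objective.
#'
#' @param name Label for the configuration.
#' @param estimated_groups Character vector of group labels, see
#'   [parameter_groups()].
#' @param ssel_surveys Which surveys' selectivities are estimated when the
#'   `"ssel"` group is active (integer vector, subset of 1:6).
#' @param n_replicates Number of phase-randomized replicates per run.
#' @param max_reorderings Maximum random phase reorderings per replicate
#'   before giving up on an invertible Hessian.
#' @param n_phases Number of phases groups are scattered into.
#' @param terminal_phase Last phase; phases beyond `n_phases` re-optimize
#'   the full active set.
#' @param penalty_weights Named list of penalty weights, see
#'   [penalty_weights()].
#' @param bias_correct Apply the lognormal bias correction (-sigma_R^2/2) to
#'   recruitment deviations so mean recruitment is a mean, not a median.
#' @param rng_seed Default seed for stochastic stages.
#' @return An object of class `krill_config`.
#' @export
configuration <- function(name = "custom",
                          estimated_groups = c("R0", "Rbar", "epsR"),
                          ssel_surveys = 1:6,
                          n_replicates = 20,
                          max_reorderings = 3000,
                          n_phases = 7,
                          terminal_phase = 9,
                          penalty_weights = krillphase::penalty_weights(),
                          bias_correct = TRUE,
                          rng_seed = 1L) {
  estimated_groups <- unique(as.character(estimated_groups))
  if (length(estimated_groups) == 0) stop("estimated_groups must be nonempty")
  unknown <- setdiff(estimated_groups, parameter_groups(TRUE))
  if (length(unknown) > 0) {
    stop("unknown parameter group(s): ", paste(unknown, collapse = ", "))
  }
  stopifnot(n_phases >= 1, terminal_phase >= n_phases, n_replicates >= 1)
  structure(list(name = name,
                 estimated_groups = estimated_groups,
                 ssel_surveys = as.integer(ssel_surveys),
                 n_replicates = as.integer(n_replicates),
                 max_reorderings = as.integer(max_reorderings),
                 n_phases = as.integer(n_phases),
                 terminal_phase = as.integer(terminal_phase),
                 penalty_weights = penalty_weights,
                 bias_correct = isTRUE(bias_correct),
                 rng_seed = as.integer(rng_seed)),
            class = "krill_config")
}

#' @export
print.krill_config <- function(x, ...) {
  cat("<krill_config> ", x$name, "\n", sep = "")
  cat("  estimated groups: ", paste(x$estimated_groups, collapse = ", "),
      "\n", sep = "")
  if ("ssel" %in% x$estimated_groups) {
    cat("  survey selectivities estimated: ",
        paste(x$ssel_surveys, collapse = ","), "\n", sep = "")
  }
  cat("  parameters: ", count_parameters(x), "\n", sep = "")
  cat("  replicates: ", x$n_replicates, ", phases: 1..", x$n_phases,
      " (terminal ", x$terminal_phase, "), max reorderings: ",
      x$max_reorderings, "\n", sep = "")
  invisible(x)
}

#' Penalty weights for the objective
#'
#' Weights of the recruitment penalties (lambda1-lambda4) and the
#' fishing-mortality penalties (lambda5, lambda6). lambda1 scales the
#' lognormal recruitment-deviation term (kept at 1 so it acts like a
#' likelihood); lambda2/lambda3 weight the squared difference between log
#' recruitment and the deterministic Beverton-Holt expectation in the
#' estimation and pre-data years; lambda4 shrinks the mean deviation toward
#' zero; lambda5 shrinks the annual log-F deviations; lambda6 is a
#' one-sided quadratic on F above `f_cap`. Setting lambda5 = lambda6 = 0
#' reproduces the penalty-removal experiment for fishing mortality.
#'
#' @param lambda1,lambda2,lambda3,lambda4,lambda5,lambda6 Non-negative
#'   weights.
#' @param f_cap Fishing mortality (per year) above which lambda6 applies.
#' @return Named list of weights.
#' @export
penalty_weights <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1,
                            lambda4 = 0.1, lambda5 = 0.1, lambda6 = 10,
                            f_cap = 1.5) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda4 = lambda4, lambda5 = lambda5, lambda6 = lambda6,
            f_cap = f_cap)
  if (any(unlist(w) < 0)) stop("penalty weights must be >= 0")
  w
}

# The 22 named configurations of the Subarea 48.1 krill assessment grid,
# ordered by increasing numbers of estimated parameters. XV and XVI share a
# group set (they differ in which pre-specified selectivity values the
# non-estimated surveys use).
preset_grid <- function() {
  base <- c("R0", "Rbar", "epsR")
  list(
    I     = list(groups = base,                                        ssel = integer()),
    II    = list(groups = c(base, "M"),                                ssel = integer()),
    III   = list(groups = c(base, "qf"),                               ssel = integer()),
    IV    = list(groups = c(base, "sigmaR"),                           ssel = integer()),
    V     = list(groups = c(base, "h"),                                ssel = integer()),
    VI    = list(groups = c(base, "M", "fsel"),                        ssel = integer()),
    VII   = list(groups = c(base, "qs"),                               ssel = integer()),
    VIII  = list(groups = c(base, "M", "fsel", "ssel"),                ssel = 1:6),
    IX    = list(groups = c(base, "F"),                                ssel = integer()),
    X     = list(groups = c(base, "F", "M"),                           ssel = integer()),
    XI    = list(groups = c(base, "F", "qf"),                          ssel = integer()),
    XII   = list(groups = c(base, "F", "qf", "sigmaR"),                ssel = integer()),
    XIII  = list(groups = c(base, "F", "M", "fsel"),                   ssel = integer()),
    XIV   = list(groups = c(base, "F", "M", "fsel", "qf"),             ssel = integer()),
    XV    = list(groups = c(base, "F", "M", "fsel", "ssel", "qf"),     ssel = 3L),
    XVI   = list(groups = c(base, "F", "M", "fsel", "ssel", "qf"),     ssel = 3L),
    XVII  = list(groups = c(base, "F", "M", "fsel", "ssel", "qf"),     ssel = 2:6),
    XVIII = list(groups = c(base, "F", "fsel", "ssel"),                ssel = 1:6),
    XIX   = list(groups = c(base, "F", "M", "fsel", "ssel"),           ssel = 1:6),
    XX    = list(groups = c(base, "F", "M", "fsel", "ssel", "qf"),     ssel = 1:6),
    XXI   = list(groups = c(base, "F", "M", "fsel", "ssel", "qf", "h"), ssel = 1:6),
    XXII  = list(groups = c(base, "F", "M", "fsel", "ssel", "qf", "sigmaR"), ssel = 1:6)
  )
}

#' Named preset configurations
#'
#' The 22 named configurations (I-XXII) of the Subarea 48.1 krill
#' assessment grid, ordered by increasing numbers of estimated parameters
#' (48 to 107). Configuration I estimates recruitment only; later
#' configurations add annual fishing mortality, natural mortality, fishery
#' and survey selectivities, fishery catchability, steepness or recruitment
#' variability. XV-XVII estimate selectivity for subsets of the six
#' surveys.
#'
#' @param name Roman-numeral label, `"I"` to `"XXII"` (a `"cfg"` prefix is
#'   accepted).
#' @param ... Passed to [configuration()] to override policy defaults.
#' @return A `krill_config`.
#' @export
#' @examples
#' count_parameters(preset_configuration("cfgI")) # 48
preset_configuration <- function(name, ...) {
  key <- sub("^cfg", "", name)
  grid <- preset_grid()
  if (!key %in% names(grid)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(grid), collapse = ", "))
  }
  p <- grid[[key]]
  configuration(name = paste0("cfg", key), estimated_groups = p$groups,
                ssel_surveys = p$ssel, ...)
}

#' Names of all preset configurations
#' @return Character vector `"I"` ... `"XXII"`.
#' @export
preset_names <- function() names(preset_grid())
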