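#' Trajectory implied by a fit
#'
#' @param fit A `krill_fit`.
#' @return The `krill_trajectory` at the fitted parameters on the fitted
#'   data bundle.
#' @export
fit_trajectory <- function(fit) {
  project(fit$params, fit$data, fit$config)
}

#' Generate error-free pseudo-data from a fit
#'
#' Replaces every observed series in the template bundle by the model's
#' predicted values at the fitted parameters. Observation years, CVs and
#' effective sample sizes are copied from the template; no observation
#' noise is added.
#'
#' @param fit The operating-model `krill_fit`.
#' @param template Data bundle supplying the observation design (defaults
#'   to the bundle the fit used).
#' @return A `krill_data` bundle of predicted values.
#' @export
generate_pseudodata <- function(fit, template = fit$data) {
  if (!identical(as.integer(template$years), as.integer(fit$data$years))) {
    stop("template and fit cover different model years")
  }
  traj <- fit_trajectory(fit)
  fill_bundle(template, traj, noise = FALSE,
              sigma_c = fit$params$value[fit$params$name == "sigma_C"])
}

#' Operating-/estimating-model cross-test
#'
#' Fits the operating configuration to the data, generates error-free
#' pseudo-data from its predictions, refits the estimating configuration
#' to the pseudo-data with phase-randomized replicates, and compares the
#' estimated trajectories (recruitment, spawning biomass, fishing
#' mortality, catches) with the operating values. With
#' `estimating = operating` this is a self-test.
#'
#' @param operating,estimating `krill_config` objects (pass the same
#'   object, or use [self_test()], for a self-test).
#' @param data A `krill_data` bundle.
#' @param n_replicates Estimating-model replicates (default 5).
#' @param operating_replicates Replicates for the operating fit.
#' @param seed Master seed.
#' @param recovery_tol Relative-error tolerance for the per-year recovery
#'   flags (default 1%).
#' @param operating_fit Optionally supply an existing operating fit and
#'   skip refitting it.
#' @return An object of class `krill_simtest`: trajectory comparison
#'   tibble, per-replicate objective values, per-quantity pass flags, and
#'   an F-bias summary over the top-quartile-F years.
#' @export
cross_test <- function(operating, estimating, data,
                       n_replicates = 5, operating_replicates = 1,
                       seed = 1L, recovery_tol = 0.01,
                       operating_fit = NULL) {
  if (is.null(operating_fit)) {
    op <- run_replicates(operating, data,
                         n_replicates = operating_replicates, seed = seed)
    operating_fit <- op$best
  }
  pseudo <- generate_pseudodata(operating_fit, data)
  est <- run_replicates(estimating, pseudo, n_replicates = n_replicates,
                        seed = derive_seed(seed, 977L))
  op_traj <- fit_trajectory(operating_fit)
  est_traj <- fit_trajectory(est$best)
  comp <- tibble::tibble(
    year = rep(data$years, times = 4),
    quantity = rep(c("recruits", "ssb", "f", "catch"),
                   each = length(data$years)),
    operating = c(op_traj$by_year$recruits, op_traj$by_year$ssb,
                  op_traj$by_year$f, op_traj$by_year$catch_pred),
    estimated = c(est_traj$by_year$recruits, est_traj$by_year$ssb,
                  est_traj$by_year$f, est_traj$by_year$catch_pred))
  comp$rel_error <- (comp$estimated - comp$operating) / comp$operating
  pass <- comp |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(max_abs_rel_error = max(abs(.data$rel_error)),
                     pass = .data$max_abs_rel_error <= recovery_tol)
  # F bias over the years with the highest operating fishing mortality
  f_op <- op_traj$by_year$f
  hi <- f_op >= stats::quantile(f_op, 0.75)
  f_bias <- mean((est_traj$by_year$f[hi] - f_op[hi]) / f_op[hi])
  nlls <- est$summary$nll
  structure(list(
    operating = operating$name, estimating = estimating$name,
    self_test = identical(operating$name, estimating$name) &&
      setequal(operating$estimated_groups, estimating$estimated_groups),
    comparison = comp, pass = pass,
    replicate_nll = nlls,
    n_at_best = sum(nlls <= min(nlls) + 0.5),
    f_bias_high_f = f_bias,
    high_f_years = data$years[hi],
    operating_fit = operating_fit, estimating_run = est),
    class = "krill_simtest")
}

#' Self-test of a configuration
#'
#' @inheritParams cross_test
#' @param config The configuration used as both operating and estimating
#'   model.
#' @param ... Passed to [cross_test()].
#' @return A `krill_simtest`, see [cross_test()].
#' @export
self_test <- function(config, data, ...) {
  cross_test(config, config, data, ...)
}

#' @export
print.krill_simtest <- function(x, ...) {
  kind <- if (x$self_test) "self-test" else "cross-test"
  cat("<krill_simtest> ", kind, ": operating ", x$operating,
      ", estimating ", x$estimating, "\n", sep = "")
  p <- x$pass
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-9s max |rel error| = %.4g  %s\n", p$quantity[i],
                p$max_abs_rel_error[i],
                if (p$pass[i]) "(recovered)" else ""))
  }
  cat("  replicates at best objective: ", x$n_at_best, "/",
      length(x$replicate_nll), "\n", sep = "")
  cat("  F bias over top-quartile-F years: ",
      format(x$f_bias_high_f, digits = 3), "\n", sep = "")
  invisible(x)
}
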