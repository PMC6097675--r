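#' Lognormal negative log-likelihood for positive series
#'
#' Contribution of a lognormally distributed series (biomass indices,
#' catches) with per-point CV: `sum(log(sigma) + log(obs/pred)^2 /
#' (2 sigma^2))` with `sigma^2 = log(1 + CV^2)`. Constants not involving
#' the parameters (`0.5 log(2 pi)` and `log(obs)`) are dropped, so for a
#' fixed CV the minimum over predictions is attained at `pred = obs`.
#'
#' @param observed,predicted Positive series of equal length.
#' @param cv Per-point CV(s) (> 0), recycled.
#' @return Scalar NLL contribution.
#' @export
lognormal_nll <- function(observed, predicted, cv) {
  if (any(observed <= 0) || any(predicted <= 0)) {
    stop("lognormal series must be strictly positive")
  }
  if (any(cv <= 0)) stop("cv must be > 0")
  sig2 <- log(1 + cv^2)
  sum(0.5 * log(sig2) + log(observed / predicted)^2 / (2 * sig2))
}

#' Multinomial negative log-likelihood for a length composition
#'
#' `-N * sum(obs_b * log(pred_b))` with predicted proportions floored at
#' 1e-10 before the log; the `obs * log(obs)` constant is dropped, so the
#' minimum over predictions is the observed entropy times N.
#'
#' @param observed_props,predicted_props Proportion vectors summing to 1
#'   (within 1e-6).
#' @param effective_n Effective sample size (> 0).
#' @return Scalar NLL contribution.
#' @export
multinomial_nll <- function(observed_props, predicted_props, effective_n) {
  if (effective_n <= 0) stop("effective_n must be > 0")
  if (abs(sum(observed_props) - 1) > 1e-6 ||
      abs(sum(predicted_props) - 1) > 1e-6) {
    stop("composition rows must sum to 1")
  }
  keep <- observed_props > 0
  -effective_n * sum(observed_props[keep] *
                       log(pmax(predicted_props[keep], 1e-10)))
}

#' Recruitment penalties (lambda1-lambda4)
#'
#' The penalty stack on annual recruitment deviations: lambda1 is the
#' lognormal deviation penalty `sum(eps^2) / (2 sigma_R^2) +
#' n * log(sigma_R)`; lambda2 the squared difference between log
#' recruitment and the log deterministic Beverton-Holt expectation (lagged
#' spawning biomass; unfished biomass for the first year) over the
#' estimation years; lambda3 quadratic shrinkage of the pre-data
#' deviations; lambda4 a penalty on the mean of all deviations toward
#' zero.
#'
#' @param eps_r All recruitment deviations (pre-data years first).
#' @param ln_sigma_r Log recruitment SD.
#' @param recruits Recruit numbers per model year.
#' @param ssb Spawning biomass per model year (tonnes).
#' @param h,r0,b0 Beverton-Holt steepness, unfished recruitment, unfished
#'   spawning biomass.
#' @param n_pre Number of pre-data deviations at the head of `eps_r`.
#' @param weights Penalty weights, see [penalty_weights()].
#' @return Named numeric vector `lambda1` ... `lambda4`.
#' @export
recruitment_penalty <- function(eps_r, ln_sigma_r, recruits, ssb, h, r0, b0,
                                n_pre = 0, weights = penalty_weights()) {
  sig <- exp(ln_sigma_r)
  if (!is.finite(sig) || sig <= 0) stop("sigma_R must be > 0")
  n <- length(eps_r)
  lam1 <- weights$lambda1 * (sum(eps_r^2) / (2 * sig^2) + n * log(sig))
  s_prev <- c(b0, ssb[-length(ssb)])
  bh <- beverton_holt(s_prev, h, r0, b0)
  lam2 <- weights$lambda2 * sum((log(recruits) - log(bh))^2)
  pre <- if (n_pre > 0) eps_r[seq_len(n_pre)] else numeric()
  lam3 <- weights$lambda3 * sum(pre^2)
  lam4 <- weights$lambda4 * n * mean(eps_r)^2
  c(lambda1 = lam1, lambda2 = lam2, lambda3 = lam3, lambda4 = lam4)
}

#' Fishing-mortality penalties (lambda5, lambda6)
#'
#' lambda5 shrinks the annual log-F deviations quadratically; lambda6 is a
#' one-sided quadratic on annual F above `f_cap`. Both are zero when their
#' weights are zero (the penalty-removal experiment).
#'
#' @param eps_f Annual log-F deviations.
#' @param f Annual fishing mortality (per year).
#' @param weights Penalty weights, see [penalty_weights()].
#' @return Named numeric vector `lambda5`, `lambda6`.
#' @export
f_penalty <- function(eps_f, f, weights = penalty_weights()) {
  c(lambda5 = weights$lambda5 * sum(eps_f^2),
    lambda6 = weights$lambda6 * sum(pmax(0, f - weights$f_cap)^2))
}
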