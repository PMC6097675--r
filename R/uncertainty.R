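# re-evaluate the full model report at a transformed parameter vector
replay_fit <- function(fit, t) {
  obj <- fit$obj_fns
  params <- obj$to_params(t)
  krill_eval_cpp(par_vector(params), obj$problem)
}

# named derived quantities from a report: "b0", "ssb_<year>",
# "recruits_<year>", "f_<year>"
derived_value <- function(rep, name, years) {
  if (name == "b0") return(rep$B0)
  parts <- strsplit(name, "_")[[1]]
  yr <- as.integer(parts[length(parts)])
  pos <- match(yr, years)
  if (is.na(pos)) stop("derived year outside the model range: ", name)
  key <- paste(parts[-length(parts)], collapse = "_")
  switch(key,
         ssb = rep$SSB[pos],
         recruits = rep$R[pos],
         f = rep$F[pos],
         stop("unknown derived quantity: ", name))
}

#' Asymptotic (delta-method) intervals
#'
#' Standard deviations for the estimated parameters from the inverse of
#' the finite-difference Hessian at the optimum, and for derived
#' quantities (unfished biomass, annual spawning biomass, recruitment,
#' fishing mortality) via a first-order Taylor expansion of the derived
#' function. Intervals are computed as estimate +/- 1.96 SD on the
#' estimation (transformed) scale and mapped back, so they respect bounds
#' and positivity.
#'
#' @param fit A converged `krill_fit`.
#' @param derived Character vector of derived-quantity names: `"b0"`,
#'   `"ssb_<year>"`, `"recruits_<year>"`, `"f_<year>"`.
#' @param level Confidence level.
#' @return A tibble with `quantity`, `estimate`, `sd`, `lower`, `upper`.
#' @export
asymptotic_intervals <- function(fit, derived = character(), level = 0.95) {
  if (is.null(fit$hessian) || !fit$pd_hessian) {
    stop("asymptotic intervals unavailable: Hessian is not invertible")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cov_t <- solve(fit$hessian)
  sd_t <- sqrt(pmax(diag(cov_t), 0))
  obj <- fit$obj_fns
  t_hat <- fit$t_hat
  x_hat <- x_from_t(t_hat, obj$type, obj$lo, obj$hi)
  back <- function(t) x_from_t(t, obj$type, obj$lo, obj$hi)
  lower <- back(t_hat - z * sd_t)
  upper <- back(t_hat + z * sd_t)
  # delta-method SD on the natural scale via d x / d t
  dxdt <- ifelse(obj$type == 1L,
                 (obj$hi - obj$lo) * stats::plogis(t_hat) *
                   (1 - stats::plogis(t_hat)),
                 ifelse(obj$type == 2L, exp(t_hat), 1))
  pars <- tibble::tibble(quantity = fit$params$name[fit$est_index],
                         estimate = x_hat, sd = sd_t * abs(dxdt),
                         lower = pmin(lower, upper),
                         upper = pmax(lower, upper))
  if (length(derived) == 0) return(pars)
  years <- fit$data$years
  d_fun <- function(t) {
    rep <- replay_fit(fit, t)
    vapply(derived, function(nm) derived_value(rep, nm, years), numeric(1))
  }
  est <- d_fun(t_hat)
  n <- length(t_hat)
  J <- matrix(0, length(derived), n)
  for (i in seq_len(n)) {
    h <- 1e-5 * max(1, abs(t_hat[i]))
    tp <- t_hat; tp[i] <- tp[i] + h
    tm <- t_hat; tm[i] <- tm[i] - h
    J[, i] <- (d_fun(tp) - d_fun(tm)) / (2 * h)
  }
  sd_d <- sqrt(pmax(diag(J %*% cov_t %*% t(J)), 0))
  der <- tibble::tibble(quantity = derived, estimate = est, sd = sd_d,
                        lower = est - z * sd_d, upper = est + z * sd_d)
  dplyr::bind_rows(pars, der)
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Samples a target density given by its negative log using a multivariate
#' normal proposal with a supplied covariance (typically the inverse
#' Hessian scaled by 2.4^2/d). An optional adaptive pre-phase tunes a
#' scalar step multiplier toward a workable acceptance rate and is frozen
#' before any recorded sample, preserving detailed balance for the
#' recorded chain.
#'
#' @param neg_log_density `function(x) -> scalar` negative log target.
#' @param start Start vector.
#' @param proposal_cov Proposal covariance matrix.
#' @param n_total Total recorded-phase iterations.
#' @param thin Save every `thin`-th sample.
#' @param burn_in Iterations discarded before saving starts;
#'   `floor((n_total - burn_in) / thin)` samples are saved.
#' @param seed RNG seed.
#' @param adapt Run the adaptive pre-phase.
#' @return List with `samples` (matrix saved x d), `acceptance_rate`
#'   (recorded phase), `scale` (frozen step multiplier), `n_total`,
#'   `thin`, `burn_in`.
#' @export
mh_sample <- function(neg_log_density, start, proposal_cov,
                      n_total = 100000, thin = 20,
                      burn_in = floor(n_total / 10), seed = 1L,
                      adapt = TRUE) {
  d <- length(start)
  L <- tryCatch(chol(proposal_cov), error = function(e) NULL)
  if (is.null(L)) stop("degenerate proposal covariance: MCMC unavailable")
  set.seed(seed)
  x <- start
  fx <- neg_log_density(x)
  if (!is.finite(fx)) stop("non-finite density at the MCMC start")
  log_scale <- 0
  step <- function() drop(crossprod(L, stats::rnorm(d))) * exp(log_scale)
  if (adapt) {
    for (batch in seq_len(25)) {
      acc <- 0L
      for (i in seq_len(200)) {
        xp <- x + step()
        fp <- neg_log_density(xp)
        if (is.finite(fp) && log(stats::runif(1)) < fx - fp) {
          x <- xp; fx <- fp; acc <- acc + 1L
        }
      }
      rate <- acc / 200
      if (rate > 0.15 && rate < 0.45) break
      log_scale <- log_scale + 0.7 * (rate - 0.3)
    }
  }
  n_save <- floor((n_total - burn_in) / thin)
  samples <- matrix(NA_real_, n_save, d)
  acc <- 0L
  k <- 0L
  for (i in seq_len(n_total)) {
    xp <- x + step()
    fp <- neg_log_density(xp)
    if (is.finite(fp) && log(stats::runif(1)) < fx - fp) {
      x <- xp; fx <- fp; acc <- acc + 1L
    }
    if (i > burn_in && (i - burn_in) %% thin == 0) {
      k <- k + 1L
      samples[k, ] <- x
    }
  }
  list(samples = samples, acceptance_rate = acc / n_total,
       scale = exp(log_scale), n_total = n_total, thin = thin,
       burn_in = burn_in)
}

#' MCMC sampling of an assessment posterior
#'
#' Metropolis-Hastings sampling of the penalized-likelihood posterior of a
#' converged fit, with a multivariate normal proposal scaled from the
#' inverse Hessian (2.4^2/d). Monitored quantities are all estimated
#' scalar (non-year-indexed) parameters plus spawning biomass and
#' recruitment in a monitor year and one fishing-mortality deviation,
#' capped at 27; their chains are computed by replaying the model at each
#' saved draw.
#'
#' @param fit A converged `krill_fit` with a positive-definite Hessian.
#' @param n_total,thin,burn_in,seed Passed to [mh_sample()].
#' @param monitor_year Year for the monitored spawning biomass and
#'   recruitment (default 2015 when inside the model span, else the last
#'   model year).
#' @param eps_f_year Year of the monitored fishing-mortality deviation.
#' @param max_monitor Cap on the number of monitored quantities.
#' @return An object of class `krill_mcmc` with `chains` (saved samples x
#'   monitored quantities, on natural scales), `par_samples` (transformed
#'   scale), `acceptance_rate`, and the thinning bookkeeping.
#' @export
mcmc_sample <- function(fit, n_total = 100000, thin = 20,
                        burn_in = floor(n_total / 10), seed = 1L,
                        monitor_year = NULL, eps_f_year = 2011,
                        max_monitor = 27) {
  if (!fit$pd_hessian) {
    stop("MCMC unavailable: Hessian is not positive definite")
  }
  d <- length(fit$t_hat)
  cov_t <- solve(fit$hessian) * (2.4^2 / d)
  res <- mh_sample(function(t) fit$obj_fns$fn(t), fit$t_hat, cov_t,
                   n_total = n_total, thin = thin, burn_in = burn_in,
                   seed = seed)
  years <- fit$data$years
  if (is.null(monitor_year)) {
    monitor_year <- if (2015 %in% years) 2015L else max(years)
  }
  p <- fit$params
  est <- fit$est_index
  scalar_idx <- est[is.na(p$year[est])]
  labels <- p$name[scalar_idx]
  derived <- c(paste0("ssb_", monitor_year), paste0("recruits_", monitor_year))
  eps_name <- paste0("eps_f_", eps_f_year)
  eps_idx <- integer()
  if (eps_name %in% p$name[est]) {
    eps_idx <- which(p$name == eps_name)
    labels <- c(labels, eps_name)
  }
  monitored <- c(labels, derived)
  if (length(monitored) > max_monitor) {
    monitored <- monitored[seq_len(max_monitor)]
  }
  obj <- fit$obj_fns
  chains <- matrix(NA_real_, nrow(res$samples), length(monitored),
                   dimnames = list(NULL, monitored))
  for (i in seq_len(nrow(res$samples))) {
    params_i <- obj$to_params(res$samples[i, ])
    vals <- params_i$value[c(scalar_idx, eps_idx)]
    need_derived <- intersect(derived, monitored)
    if (length(need_derived) > 0) {
      rep_i <- krill_eval_cpp(par_vector(params_i), obj$problem)
      vals <- c(vals, vapply(need_derived, function(nm) {
        derived_value(rep_i, nm, years)
      }, numeric(1)))
    }
    chains[i, ] <- vals[seq_len(length(monitored))]
  }
  structure(list(chains = chains, par_samples = res$samples,
                 acceptance_rate = res$acceptance_rate,
                 scale = res$scale, n_total = res$n_total,
                 thin = res$thin, burn_in = res$burn_in,
                 monitor_year = monitor_year),
            class = "krill_mcmc")
}

#' @export
print.krill_mcmc <- function(x, ...) {
  cat("<krill_mcmc> ", nrow(x$chains), " saved samples of ",
      ncol(x$chains), " monitored quantities\n", sep = "")
  cat("  n_total = ", x$n_total, ", thin = ", x$thin, ", burn-in = ",
      x$burn_in, ", acceptance rate = ",
      format(x$acceptance_rate, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Heidelberger-Welch diagnostics for one chain
#'
#' Stationarity via the Cramer-von Mises test with the iterative 10%
#' discard schedule, and the halfwidth test (95% interval halfwidth below
#' 10% of the mean, with spectral variance at frequency zero). A constant
#' chain has an undefined halfwidth and is flagged as a pass with a
#' warning note.
#'
#' @param chain Numeric vector (length >= 100).
#' @param eps Halfwidth tolerance (fraction of the mean).
#' @param pvalue Stationarity test level.
#' @return One-row tibble: `stationarity_pass`, `kept_fraction`,
#'   `halfwidth_pass` (`NA` when inapplicable), `mean`, `halfwidth`,
#'   `note`.
#' @export
heidelberger_welch <- function(chain, eps = 0.1, pvalue = 0.05) {
  stopifnot(length(chain) >= 100)
  if (stats::sd(chain) == 0) {
    return(tibble::tibble(stationarity_pass = TRUE, kept_fraction = 1,
                          halfwidth_pass = NA, mean = mean(chain),
                          halfwidth = NA_real_,
                          note = "constant chain: halfwidth undefined"))
  }
  hd <- coda::heidel.diag(coda::mcmc(chain), eps = eps, pvalue = pvalue)
  st <- isTRUE(hd[1, "stest"] == 1)
  kept <- 1 - (hd[1, "start"] - 1) / length(chain)
  m <- hd[1, "mean"]
  hw <- hd[1, "halfwidth"]
  note <- ""
  if (!st) {
    hw_pass <- NA
    note <- "stationarity failed; halfwidth not assessed"
  } else if (!is.finite(m) || abs(m) < sqrt(.Machine$double.eps)) {
    hw_pass <- NA
    note <- "mean near zero: relative halfwidth inapplicable"
  } else {
    hw_pass <- isTRUE(hd[1, "htest"] == 1)
  }
  tibble::tibble(stationarity_pass = st, kept_fraction = kept,
                 halfwidth_pass = hw_pass, mean = m, halfwidth = hw,
                 note = note)
}

#' Geweke score, autocorrelations and effective size
#'
#' Geweke's convergence z-score comparing the first 10% and last 50% of
#' the chain (spectral variance estimates), lag-1..`max_lag`
#' autocorrelations, and the effective sample size.
#'
#' @param chain Numeric vector (length >= 100).
#' @param max_lag Largest autocorrelation lag reported.
#' @return List with `z`, `acf` (tibble `lag`, `autocorrelation`), `ess`.
#' @export
geweke_and_acf <- function(chain, max_lag = 50) {
  stopifnot(length(chain) >= 100)
  z <- unname(coda::geweke.diag(coda::mcmc(chain),
                                frac1 = 0.1, frac2 = 0.5)$z)
  ac <- stats::acf(chain, lag.max = max_lag, plot = FALSE)$acf[-1]
  ess <- unname(coda::effectiveSize(coda::mcmc(chain)))
  list(z = z,
       acf = tibble::tibble(lag = seq_len(max_lag),
                            autocorrelation = as.numeric(ac)),
       ess = ess)
}

#' Convergence diagnostics report for an MCMC run
#'
#' Applies [heidelberger_welch()] and [geweke_and_acf()] to every
#' monitored quantity. The overall pass requires every quantity to pass
#' stationarity and (where applicable) the halfwidth test.
#'
#' @param mcmc A `krill_mcmc` (or any matrix of chains with column names).
#' @return List with `table` (per-quantity tibble) and `pass` (logical).
#' @export
diagnostics_report <- function(mcmc) {
  chains <- if (inherits(mcmc, "krill_mcmc")) mcmc$chains else as.matrix(mcmc)
  rows <- purrr::map_dfr(seq_len(ncol(chains)), function(j) {
    hw <- heidelberger_welch(chains[, j])
    gw <- geweke_and_acf(chains[, j])
    dplyr::mutate(hw, quantity = colnames(chains)[j],
                  geweke_z = gw$z, ess = gw$ess, .before = 1)
  })
  pass <- all(rows$stationarity_pass) &
    all(rows$halfwidth_pass | is.na(rows$halfwidth_pass))
  list(table = rows, pass = pass)
}
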