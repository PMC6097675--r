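# smooth transforms used on the estimation scale: identity, logit between
# bounds, log for positive spreads
transform_code <- function(transform) {
  match(transform, c("identity", "logit", "log")) - 1L
}

t_from_x <- function(x, type, lo, hi) {
  out <- x
  is_logit <- type == 1L
  p <- (x[is_logit] - lo[is_logit]) / (hi[is_logit] - lo[is_logit])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  out[is_logit] <- log(p / (1 - p))
  out[type == 2L] <- log(x[type == 2L])
  out
}

x_from_t <- function(t, type, lo, hi) {
  out <- t
  is_logit <- type == 1L
  out[is_logit] <- lo[is_logit] +
    (hi[is_logit] - lo[is_logit]) * stats::plogis(t[is_logit])
  out[type == 2L] <- exp(t[type == 2L])
  out
}

#' Draw a random phase assignment
#'
#' Assigns each estimated parameter group a uniformly random activation
#' phase in `1..n_phases`. Groups activated in earlier phases are
#' re-estimated in every later phase.
#'
#' @param config A `krill_config`.
#' @param seed RNG seed (reproducible assignment).
#' @return Named integer vector, one phase per estimated group.
#' @export
assign_random_phases <- function(config, seed = config$rng_seed) {
  stopifnot(config$n_phases >= 1)
  set.seed(seed)
  groups <- config$estimated_groups
  stats::setNames(sample.int(config$n_phases, length(groups),
                             replace = TRUE), groups)
}

#' Staged (phased) minimization of a generic objective
#'
#' Minimizes `fn` over a parameter vector in phases: at phase `p` only the
#' coordinates whose group was activated at a phase `<= p` are free, the
#' rest stay at their current values. Once activated, coordinates remain
#' free in all later phases; phases beyond the largest activation phase
#' re-optimize the full set.
#'
#' @param start Start vector (on whatever scale `fn` expects).
#' @param fn Objective `function(par) -> scalar`.
#' @param gr Optional gradient `function(par, which) -> numeric` returning
#'   the partials for the coordinate subset `which`.
#' @param groups Group label per coordinate of `start`.
#' @param phases Named integer vector, activation phase per group.
#' @param terminal_phase Last phase to run.
#' @param control Passed to [stats::nlminb()].
#' @return List with `par`, `objective`, and `phase_objective` (objective
#'   value at the end of each executed phase).
#' @export
phased_optim <- function(start, fn, gr = NULL, groups, phases,
                         terminal_phase = max(phases),
                         control = list(iter.max = 500, eval.max = 1000,
                                        rel.tol = 1e-12)) {
  par <- start
  phase_obj <- numeric(0)
  best <- fn(par)
  for (p in seq_len(terminal_phase)) {
    free <- which(phases[groups] <= p)
    if (length(free) == 0) {
      phase_obj <- c(phase_obj, best)
      next
    }
    sub_fn <- function(ts) {
      full <- par
      full[free] <- ts
      fn(full)
    }
    sub_gr <- if (!is.null(gr)) {
      function(ts) {
        full <- par
        full[free] <- ts
        gr(full, free)
      }
    } else NULL
    opt <- stats::nlminb(par[free], sub_fn, gradient = sub_gr,
                         control = control)
    if (is.finite(opt$objective) && opt$objective <= best) {
      par[free] <- opt$par
      best <- opt$objective
    }
    phase_obj <- c(phase_obj, best)
  }
  list(par = par, objective = best, phase_objective = phase_obj)
}

# closures evaluating the assessment objective on the transformed scale
make_objective <- function(data, config, params = default_parameters()) {
  pb <- build_problem(data, config)
  idx <- estimated_index(config, params)
  par_full <- par_vector(params)
  type <- transform_code(params$transform[idx])
  lo <- params$lower[idx]
  hi <- params$upper[idx]
  t0 <- t_from_x(params$value[idx], type, lo, hi)
  idx0 <- as.integer(idx - 1L)
  list(
    fn = function(t) krill_nll_t_cpp(t, par_full, idx0, type, lo, hi, pb),
    gr = function(t, which = seq_along(t)) {
      krill_grad_t_cpp(t, par_full, idx0, type, lo, hi, pb,
                       as.integer(which - 1L))
    },
    hess = function(t) krill_hess_t_cpp(t, par_full, idx0, type, lo, hi, pb),
    to_params = function(t) {
      params$value[idx] <- x_from_t(t, type, lo, hi)
      params
    },
    t0 = t0, idx = idx, type = type, lo = lo, hi = hi,
    problem = pb, params = params)
}

#' Fit one phase-randomized replicate
#'
#' Runs the staged minimization for a configuration under one phase
#' assignment, starting every quantity at its pre-specified initial value,
#' then evaluates the gradient and a finite-difference Hessian at the
#' optimum. Bounded parameters are optimized through smooth (logit/log)
#' transforms so estimates stay strictly inside bounds; estimates close to
#' a bound are flagged. The fit converged when the symmetrized Hessian is
#' positive definite with condition number below 1e12 and the maximum
#' absolute gradient (transformed scale) is below 0.001.
#'
#' @param config A `krill_config`.
#' @param data A `krill_data` bundle.
#' @param assignment Phase assignment from [assign_random_phases()].
#' @param params Starting parameter table.
#' @param compute_hessian Set `FALSE` to skip the Hessian (e.g. inside
#'   exploratory loops).
#' @return An object of class `krill_fit`.
#' @export
phased_minimize <- function(config, data,
                            assignment = assign_random_phases(config),
                            params = default_parameters(data$years,
                                                        data$n_ages,
                                                        length(data$surveys)),
                            compute_hessian = TRUE) {
  obj <- make_objective(data, config, params)
  groups <- params$group[obj$idx]
  opt <- phased_optim(obj$t0, obj$fn, obj$gr, groups, assignment,
                      terminal_phase = config$terminal_phase)
  t_hat <- opt$par
  best_obj <- opt$objective
  g <- obj$gr(t_hat)
  max_g <- max(abs(g))
  H <- NULL; pd <- FALSE; cond_ok <- FALSE
  if (compute_hessian) {
    hess_eval <- function(t) {
      Hs <- obj$hess(t)
      Hs <- (Hs + t(Hs)) / 2
      ev <- tryCatch(eigen(Hs, symmetric = TRUE, only.values = TRUE)$values,
                     error = function(e) NA_real_)
      list(H = Hs, ev = ev,
           pd = all(is.finite(ev)) && min(ev) > 0)
    }
    he <- hess_eval(t_hat)
    # Newton polish: the quasi-Newton stop can leave the gradient a touch
    # above the gate even at the right optimum
    polish <- 0L
    while (he$pd && max_g >= 1e-3 && polish < 3L) {
      step <- tryCatch(solve(he$H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- t_hat - step
      f_cand <- obj$fn(cand)
      if (!is.finite(f_cand) || f_cand > best_obj + 1e-8) break
      t_hat <- cand
      best_obj <- f_cand
      g <- obj$gr(t_hat)
      max_g <- max(abs(g))
      polish <- polish + 1L
    }
    if (polish > 0L) he <- hess_eval(t_hat)
    H <- he$H
    pd <- he$pd
    cond_ok <- pd && (max(he$ev) / min(he$ev) < 1e12)
    opt$objective <- best_obj
  }
  fitted_params <- obj$to_params(t_hat)
  x_hat <- fitted_params$value[obj$idx]
  span <- ifelse(obj$type == 1L, (x_hat - obj$lo) / (obj$hi - obj$lo), NA)
  at_bound <- any(span < 1e-4 | span > 1 - 1e-4, na.rm = TRUE)
  if (at_bound) {
    warning("estimates of bounded parameters should be checked after ",
            "estimation: at least one estimate is near a bound")
  }
  structure(list(
    config = config, data = data, params = fitted_params,
    t_hat = t_hat, est_index = obj$idx,
    objective = opt$objective, phase_objective = opt$phase_objective,
    gradient = as.numeric(g), max_gradient = max_g,
    hessian = H, pd_hessian = pd && cond_ok,
    converged = pd && cond_ok && max_g < 1e-3,
    at_bound = at_bound,
    assignment = assignment,
    nll = total_objective(fitted_params, data, config),
    obj_fns = obj), class = "krill_fit")
}

#' @export
print.krill_fit <- function(x, ...) {
  cat("<krill_fit> ", x$config$name, ": ", length(x$est_index),
      " estimated parameters\n", sep = "")
  cat("  objective = ", format(x$objective, digits = 8),
      ", max |gradient| = ", format(x$max_gradient, digits = 3),
      "\n  converged = ", x$converged,
      " (positive-definite Hessian = ", x$pd_hessian, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.krill_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = p$name, group = p$group, estimate = p$value,
                 estimated = seq_len(nrow(p)) %in% x$est_index)
}

#' @export
glance.krill_fit <- function(x, ...) {
  tibble::tibble(nll = x$objective,
                 n_params = length(x$est_index),
                 max_gradient = x$max_gradient,
                 converged = x$converged,
                 pd_hessian = x$pd_hessian)
}

derive_seed <- function(master, r, k = 0L) {
  as.integer((as.numeric(master) * 1009 + r * 7919 + k * 104729) %%
               2147483629)
}

#' Run phase-randomized replicates for a configuration
#'
#' Each replicate draws random phase orders until the fit passes the
#' convergence gate (invertible Hessian and maximum gradient below 0.001)
#' or `max_reorderings` is exhausted. The summary reports the median
#' number of reorderings, the percentage of replicates at the lowest
#' observed objective (ties within 0.5 objective units count as equal),
#' and the best replicate (lowest objective, then lowest maximum
#' gradient).
#'
#' @param config A `krill_config`.
#' @param data A `krill_data` bundle.
#' @param params Starting parameter table.
#' @param n_replicates,max_reorderings Override the configuration policy.
#' @param seed Master seed; replicate r uses a derived stream seed.
#' @return An object of class `krill_replicates`: list with `fits`,
#'   `summary` (per-replicate tibble), `best` (best converged fit or best
#'   overall), `median_reorderings`, `pct_best`, `all_converged`.
#' @export
run_replicates <- function(config, data,
                           params = default_parameters(data$years,
                                                       data$n_ages,
                                                       length(data$surveys)),
                           n_replicates = config$n_replicates,
                           max_reorderings = config$max_reorderings,
                           seed = config$rng_seed) {
  fits <- vector("list", n_replicates)
  reorder <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    fit <- NULL
    for (k in seq_len(max_reorderings)) {
      assignment <- assign_random_phases(config, seed = derive_seed(seed, r, k))
      fit <- phased_minimize(config, data, assignment, params)
      if (fit$converged) break
    }
    fits[[r]] <- fit
    reorder[r] <- k
  }
  nlls <- vapply(fits, function(f) f$objective, numeric(1))
  maxg <- vapply(fits, function(f) f$max_gradient, numeric(1))
  conv <- vapply(fits, function(f) f$converged, logical(1))
  best_nll <- min(nlls)
  is_best <- nlls <= best_nll + 0.5
  ord <- order(nlls, maxg)
  summary <- tibble::tibble(replicate = seq_len(n_replicates),
                            nll = nlls, max_gradient = maxg,
                            converged = conv, reorderings = reorder,
                            at_best = is_best)
  structure(list(fits = fits, summary = summary,
                 best = fits[[ord[1]]],
                 median_reorderings = stats::median(reorder),
                 pct_best = 100 * mean(is_best),
                 all_converged = all(conv),
                 any_converged = any(conv),
                 config = config, seed = seed),
            class = "krill_replicates")
}

#' @export
print.krill_replicates <- function(x, ...) {
  cat("<krill_replicates> ", x$config$name, ": ",
      nrow(x$summary), " replicates\n", sep = "")
  cat("  best objective = ", format(min(x$summary$nll), digits = 8),
      ", % best = ", x$pct_best,
      ", median reorderings = ", x$median_reorderings, "\n", sep = "")
  if (!x$any_converged) {
    cat("  NOTE: no replicate converged (non-invertible configuration)\n")
  }
  invisible(x)
}

#' @export
glance.krill_replicates <- function(x, ...) {
  tibble::tibble(name = x$config$name,
                 n_params = length(x$best$est_index),
                 median_iterations = x$median_reorderings,
                 pct_best = x$pct_best,
                 nll = x$best$objective,
                 max_gradient = x$best$max_gradient,
                 all_converged = x$all_converged)
}

#' Comparison table across fitted configurations
#'
#' Builds the per-configuration summary (parameter counts, median
#' reorderings, % best, best objective, max gradient) and the
#' delta-AIC/BIC columns relative to the best configuration.
#'
#' @param runs List of `krill_replicates` objects.
#' @param n Sample size for the BIC, see [sample_size()].
#' @return A tibble, one row per configuration.
#' @export
comparison_table <- function(runs, n) {
  base <- purrr::map_dfr(runs, glance)
  dt <- delta_table(dplyr::select(base, "name", "nll",
                                  k = "n_params"), n)
  dplyr::left_join(base, dplyr::select(dt, "name", "aic", "bic",
                                       "delta_aic", "delta_bic"),
                   by = "name")
}
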