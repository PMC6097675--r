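#' Logistic selectivity at age
#'
#' The fraction of an age class available to a gear,
#' `s(a) = 1 / (1 + exp(-(a - alpha) / beta))`: `alpha` is the age at 50%
#' selection and `beta` the spread (years). Strictly increasing in age and
#' approaching 1 for old ages; as `beta -> 0` it approaches a knife edge at
#' `alpha`.
#'
#' @param age Age(s) in years.
#' @param alpha Location (age at 50% selectivity).
#' @param beta Spread (> 0).
#' @return Selectivity in (0, 1), same length as `age`.
#' @export
#' @examples
#' logistic_selectivity(1:7, alpha = 1.3, beta = 2.8)
logistic_selectivity <- function(age, alpha, beta) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  stats::plogis((age - alpha) / beta)
}

#' Von Bertalanffy mean length at age
#'
#' `L(a) = Linf * (1 - exp(-k * a))` (mm).
#'
#' @param age Age(s) in years.
#' @param linf Asymptotic length (mm).
#' @param k Growth rate (per year).
#' @return Mean length(s), mm.
#' @export
vb_length <- function(age, linf, k) linf * (1 - exp(-k * age))

#' Age-to-length transition matrix
#'
#' Probability that an individual of each age falls into each length bin,
#' assuming length at age is normal with von Bertalanffy mean
#' `L(a) = Linf (1 - exp(-k a))` and constant spread `sigma_v`, integrated
#' over half-open bins `[lo, hi)` with the tails folded into the end bins
#' so every row sums to one.
#'
#' @param ln_linf,ln_k,ln_sigma_v Log growth parameters (defaults are the
#'   pre-specified krill values: Linf about 60.9 mm, k about 0.45 per year,
#'   sigma_v about 4.30 mm).
#' @param length_bins Bin edges (mm), increasing; `length(length_bins) - 1`
#'   bins. Default 10-70 mm in 2 mm bins.
#' @param ages Integer ages. Default 1:7.
#' @return Matrix `[age, bin]` of probabilities; rows sum to 1.
#' @export
age_length_matrix <- function(ln_linf = 4.11, ln_k = -0.799,
                              ln_sigma_v = 1.459,
                              length_bins = seq(10, 70, by = 2),
                              ages = 1:7) {
  if (length(length_bins) < 2) stop("need at least one length bin")
  if (is.unsorted(length_bins, strictly = TRUE)) {
    stop("length_bins must be strictly increasing")
  }
  linf <- exp(ln_linf); k <- exp(ln_k); sv <- exp(ln_sigma_v)
  mu <- vb_length(ages, linf, k)
  edges <- length_bins
  nb <- length(edges) - 1L
  # interior edges via the normal CDF; outer tails folded into end bins
  p <- vapply(seq_along(ages), function(i) {
    cdf <- stats::pnorm(edges, mean = mu[i], sd = sv)
    cdf[1] <- 0; cdf[length(cdf)] <- 1
    diff(cdf)
  }, numeric(nb))
  t(p)
}

#' Beverton-Holt expected recruitment
#'
#' Steepness parameterization of the Beverton-Holt spawner-recruit curve:
#' `R(S) = 4 h R0 S / (B0 (1 - h) + (5 h - 1) S)`, so that `R(B0) = R0` and
#' `R(0.2 B0) = h R0` (steepness `h` is the fraction of unfished
#' recruitment produced at 20% of unfished spawning biomass).
#'
#' @param ssb Spawning biomass (tonnes), >= 0.
#' @param h Steepness in [0.21, 1].
#' @param r0 Unfished mean recruitment (numbers).
#' @param b0 Unfished spawning biomass (tonnes), > 0.
#' @return Expected recruit numbers, same length as `ssb`.
#' @export
#' @examples
#' beverton_holt(c(0, 0.2, 1) * 500, h = 0.85, r0 = 1e6, b0 = 500)
beverton_holt <- function(ssb, h, r0, b0) {
  if (!is.finite(b0) || b0 <= 0) stop("b0 must be > 0")
  if (h < 0.21 || h > 1) stop("steepness h must be in [0.21, 1]")
  if (any(ssb < 0)) stop("ssb must be >= 0")
  4 * h * r0 * ssb / (b0 * (1 - h) + (5 * h - 1) * ssb)
}
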