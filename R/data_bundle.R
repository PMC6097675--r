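#' Assemble a data bundle
#'
#' The observation set the assessment is fitted to: per-survey annual
#' biomass indices with CVs, per-survey and fishery annual length
#' compositions with effective sample sizes, and annual fishery catches.
#' Also carries the model grid the data sit on: model years, length bins,
#' number of age classes, maturity, and the length-weight relation.
#'
#' @param surveys List of survey series; each a list with elements
#'   `name`, `index` (tibble `year`, `obs`, `cv`), `comp_years` (integer),
#'   `comps` (matrix years x bins of proportions) and `effective_n`
#'   (scalar or per-year vector).
#' @param fishery List with `catch` (tibble `year`, `obs` in tonnes),
#'   `comp_years`, `comps`, `effective_n`.
#' @param years Model years (first to last).
#' @param length_bins Length bin edges, mm (half-open bins).
#' @param n_ages Number of age classes (oldest is a plus group).
#' @param maturity_age Knife-edge age at maturity.
#' @param weight_a,weight_b Allometric length-weight coefficients,
#'   `w = a * L^b` with `w` in tonnes and `L` in mm.
#' @return An object of class `krill_data`.
#' @export
data_bundle <- function(surveys, fishery, years = 1976:2016,
                        length_bins = seq(10, 70, by = 2),
                        n_ages = 7, maturity_age = 3,
                        weight_a = 1e-9, weight_b = 3) {
  nb <- length(length_bins) - 1L
  surveys <- purrr::map(surveys, function(s) {
    s$index <- tibble::as_tibble(s$index)
    if (is.null(s$comp_years)) s$comp_years <- integer()
    s$comp_years <- as.integer(s$comp_years)
    if (is.null(s$comps)) s$comps <- matrix(0, 0, nb)
    s$effective_n <- rep_len(s$effective_n %||% numeric(),
                             length(s$comp_years))
    s
  })
  fishery$catch <- tibble::as_tibble(fishery$catch)
  fishery$comp_years <- as.integer(fishery$comp_years %||% integer())
  if (is.null(fishery$comps)) fishery$comps <- matrix(0, 0, nb)
  fishery$effective_n <- rep_len(fishery$effective_n %||% numeric(),
                                 length(fishery$comp_years))
  x <- structure(list(surveys = surveys, fishery = fishery,
                      years = as.integer(years),
                      length_bins = length_bins,
                      n_ages = as.integer(n_ages),
                      maturity_age = as.integer(maturity_age),
                      weight_a = weight_a, weight_b = weight_b),
                 class = "krill_data")
  validate_bundle(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_bundle <- function(x) {
  nb <- length(x$length_bins) - 1L
  check_series <- function(s, label) {
    if (nrow(s$index) > 0) {
      if (any(!s$index$year %in% x$years)) {
        stop(label, ": index years outside the model year range")
      }
      if (any(s$index$cv <= 0)) stop(label, ": all index CVs must be > 0")
      if (any(s$index$obs <= 0)) stop(label, ": index values must be > 0")
    }
    if (length(s$comp_years) > 0) {
      if (ncol(s$comps) != nb) stop(label, ": composition bin mismatch")
      if (nrow(s$comps) != length(s$comp_years)) {
        stop(label, ": composition rows != composition years")
      }
      if (any(abs(rowSums(s$comps) - 1) > 1e-9)) {
        stop(label, ": composition rows must sum to 1")
      }
      if (any(s$effective_n <= 0)) stop(label, ": effective N must be > 0")
      if (any(!s$comp_years %in% x$years)) {
        stop(label, ": composition years outside the model year range")
      }
    }
    invisible(NULL)
  }
  purrr::iwalk(x$surveys, function(s, i) {
    check_series(s, s$name %||% paste("survey", i))
  })
  check_series(c(x$fishery, list(index = tibble::tibble(
    year = x$fishery$catch$year, obs = x$fishery$catch$obs, cv = 1))),
    "fishery")
  x
}

#' @export
print.krill_data <- function(x, ...) {
  cat("<krill_data> years ", min(x$years), "-", max(x$years),
      ", ", length(x$surveys), " surveys, ",
      length(x$length_bins) - 1L, " length bins, ",
      x$n_ages, " ages\n", sep = "")
  for (s in x$surveys) {
    cat("  ", s$name %||% "survey", ": ", nrow(s$index), " index years, ",
        length(s$comp_years), " composition years\n", sep = "")
  }
  cat("  fishery: ", nrow(x$fishery$catch), " catch years, ",
      length(x$fishery$comp_years), " composition years\n", sep = "")
  cat("  sample size (data-years): ", sample_size(x), "\n", sep = "")
  invisible(x)
}

#' Tidy the observations of a data bundle
#'
#' @param data A `krill_data` bundle.
#' @return A long tibble with columns `series`, `type` (`index`, `comp`,
#'   `catch`), `year`, `bin` (NA for non-compositions), `value`.
#' @export
tidy_bundle <- function(data) {
  stopifnot(inherits(data, "krill_data"))
  mids <- bin_midpoints(data$length_bins)
  one <- function(name, s) {
    out <- list()
    if (nrow(s$index) > 0) {
      out$idx <- tibble::tibble(series = name, type = "index",
                                year = s$index$year, bin = NA_real_,
                                value = s$index$obs)
    }
    if (length(s$comp_years) > 0) {
      out$cmp <- tidyr::expand_grid(year = s$comp_years, bin = mids) |>
        dplyr::mutate(series = name, type = "comp",
                      value = as.vector(t(s$comps))) |>
        dplyr::select("series", "type", "year", "bin", "value")
    }
    dplyr::bind_rows(out)
  }
  svy <- purrr::imap_dfr(data$surveys, function(s, i) {
    one(s$name %||% paste0("survey_", i), s)
  })
  fsh <- dplyr::bind_rows(
    tibble::tibble(series = "fishery", type = "catch",
                   year = data$fishery$catch$year, bin = NA_real_,
                   value = data$fishery$catch$obs),
    one("fishery", list(index = tibble::tibble(year = integer(),
                                               obs = numeric(),
                                               cv = numeric()),
                        comp_years = data$fishery$comp_years,
                        comps = data$fishery$comps)))
  dplyr::bind_rows(svy, fsh)
}

bin_midpoints <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
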