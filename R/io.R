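#' Write a data bundle as CSVs plus a JSON manifest
#'
#' One CSV per series (indices, compositions, catches) and a
#' `manifest.json` recording the model grid and file layout. The CSV
#' dialect is UTF-8, comma-separated, `.` decimal, mandatory header; years
#' are integers and proportions are written at full precision.
#'
#' @param data A `krill_data` bundle.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(data, dir) {
  stopifnot(inherits(data, "krill_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mids <- bin_midpoints(data$length_bins)
  comp_df <- function(years, comps, neff) {
    df <- tibble::as_tibble(as.data.frame(comps))
    names(df) <- paste0("bin_", mids)
    dplyr::bind_cols(tibble::tibble(year = years, effective_n = neff), df)
  }
  files <- list()
  for (i in seq_along(data$surveys)) {
    s <- data$surveys[[i]]
    nm <- s$name %||% paste0("survey_", i)
    f_idx <- paste0(nm, "_index.csv")
    readr::write_csv(s$index, file.path(dir, f_idx))
    entry <- list(name = nm, index = f_idx)
    if (length(s$comp_years) > 0) {
      f_cmp <- paste0(nm, "_comps.csv")
      readr::write_csv(comp_df(s$comp_years, s$comps, s$effective_n),
                       file.path(dir, f_cmp))
      entry$comps <- f_cmp
    }
    files[[nm]] <- entry
  }
  readr::write_csv(data$fishery$catch, file.path(dir, "fishery_catch.csv"))
  fsh <- list(catch = "fishery_catch.csv")
  if (length(data$fishery$comp_years) > 0) {
    readr::write_csv(comp_df(data$fishery$comp_years, data$fishery$comps,
                             data$fishery$effective_n),
                     file.path(dir, "fishery_comps.csv"))
    fsh$comps <- "fishery_comps.csv"
  }
  manifest <- list(years = data$years, length_bins = data$length_bins,
                   n_ages = data$n_ages, maturity_age = data$maturity_age,
                   weight_a = data$weight_a, weight_b = data$weight_b,
                   surveys = unname(files), fishery = fsh)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a data bundle written by [write_bundle()]
#'
#' @param dir Directory containing `manifest.json` and the CSVs.
#' @return A `krill_data` bundle.
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  read_comps <- function(file) {
    df <- readr::read_csv(file.path(dir, file), show_col_types = FALSE)
    list(years = as.integer(df$year), neff = df$effective_n,
         comps = as.matrix(df[, startsWith(names(df), "bin_")]))
  }
  surveys <- purrr::map(seq_len(nrow(manifest$surveys)), function(i) {
    entry <- manifest$surveys[i, ]
    idx <- readr::read_csv(file.path(dir, entry$index),
                           show_col_types = FALSE)
    s <- list(name = entry$name,
              index = tibble::tibble(year = as.integer(idx$year),
                                     obs = idx$obs, cv = idx$cv))
    if (!is.null(entry$comps) && !is.na(entry$comps)) {
      cm <- read_comps(entry$comps)
      s$comp_years <- cm$years
      s$comps <- unname(cm$comps)
      s$effective_n <- cm$neff
    }
    s
  })
  ctc <- readr::read_csv(file.path(dir, manifest$fishery$catch),
                         show_col_types = FALSE)
  fishery <- list(catch = tibble::tibble(year = as.integer(ctc$year),
                                         obs = ctc$obs))
  if (!is.null(manifest$fishery$comps)) {
    cm <- read_comps(manifest$fishery$comps)
    fishery$comp_years <- cm$years
    fishery$comps <- unname(cm$comps)
    fishery$effective_n <- cm$neff
  }
  data_bundle(surveys, fishery, years = manifest$years,
              length_bins = manifest$length_bins,
              n_ages = manifest$n_ages,
              maturity_age = manifest$maturity_age,
              weight_a = manifest$weight_a, weight_b = manifest$weight_b)
}

#' Load a configuration from YAML or JSON
#'
#' A configuration file either names a preset (`preset: cfgXVI`) with
#' optional overrides, or supplies the fields of [configuration()]
#' directly. Unknown keys are rejected with a message naming the key.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `krill_config`.
#' @export
load_configuration <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  spec <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("preset", "name", "estimated_groups", "ssel_surveys",
               "n_replicates", "max_reorderings", "n_phases",
               "terminal_phase", "penalty_weights", "bias_correct",
               "rng_seed")
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(spec$penalty_weights)) {
    spec$penalty_weights <- do.call(penalty_weights, spec$penalty_weights)
  }
  if (!is.null(spec$preset)) {
    preset <- spec$preset
    spec$preset <- NULL
    do.call(preset_configuration, c(list(name = preset), spec))
  } else {
    do.call(configuration, spec)
  }
}

#' Write a parameter table to CSV
#' @param params Parameter table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}

#' Read a parameter table from CSV
#' @param path CSV written by [write_parameters()].
#' @return Parameter tibble.
#' @export
read_parameters <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    name = readr::col_character(),
                    group = readr::col_character(),
                    transform = readr::col_character(),
                    year = readr::col_integer(),
                    survey = readr::col_integer(),
                    .default = readr::col_double()))
}

#' Run the sequential assessment pipeline
#'
#' Executes the modeling stages in order on one data bundle: replicate
#' fitting, optional MCMC with convergence diagnostics, and a
#' comparison-table row. Re-running with the same seed reproduces the
#' outputs exactly.
#'
#' @param config A `krill_config`.
#' @param data A `krill_data` bundle.
#' @param n_replicates Override the configuration's replicate count.
#' @param mcmc Run the MCMC stage when the fit converged.
#' @param mcmc_n,mcmc_thin MCMC length and thinning.
#' @param seed Master seed for every stochastic stage.
#' @param out Optional output directory: per-stage CSV/JSON artifacts are
#'   written there.
#' @return List with `run` (`krill_replicates`), `mcmc` (`krill_mcmc` or
#'   `NULL`), `diagnostics`, and `row` (one comparison-table row).
#' @export
run_pipeline <- function(config, data, n_replicates = config$n_replicates,
                         mcmc = TRUE, mcmc_n = 20000, mcmc_thin = 10,
                         seed = config$rng_seed, out = NULL) {
  run <- run_replicates(config, data, n_replicates = n_replicates,
                        seed = seed)
  mc <- NULL; diag <- NULL
  if (mcmc && run$best$converged) {
    mc <- mcmc_sample(run$best, n_total = mcmc_n, thin = mcmc_thin,
                      seed = derive_seed(seed, 31L))
    diag <- diagnostics_report(mc)
  }
  row <- glance(run)
  row$coda_pass <- if (is.null(diag)) NA else diag$pass
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(run$summary, file.path(out, "replicates.csv"))
    write_parameters(run$best$params, file.path(out, "best_parameters.csv"))
    readr::write_csv(run$best$nll, file.path(out, "nll_breakdown.csv"))
    if (!is.null(mc)) {
      readr::write_csv(tibble::as_tibble(mc$chains),
                       file.path(out, "chains.csv"))
      readr::write_csv(diag$table, file.path(out, "diagnostics.csv"))
      jsonlite::write_json(list(pass = diag$pass,
                                acceptance_rate = mc$acceptance_rate,
                                n_total = mc$n_total, thin = mc$thin,
                                burn_in = mc$burn_in),
                           file.path(out, "diagnostics.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    readr::write_csv(row, file.path(out, "summary_row.csv"))
    jsonlite::write_json(list(config = config$name, seed = seed,
                              n_replicates = n_replicates,
                              stages = c("fit",
                                         if (!is.null(mc)) "mcmc",
                                         if (!is.null(diag)) "diagnose")),
                         file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(run = run, mcmc = mc, diagnostics = diag, row = row)
}
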