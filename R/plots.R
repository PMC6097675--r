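#' Plot a projected trajectory
#'
#' Panels for annual recruitment, spawning biomass, fishing mortality and
#' predicted catch.
#'
#' @param object A `krill_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.krill_trajectory <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a self-/cross-test comparison
#'
#' Operating (solid) versus estimating (dashed) trajectories per quantity.
#'
#' @param object A `krill_simtest`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.krill_simtest <- function(object, ...) {
  object$comparison |>
    tidyr::pivot_longer(c("operating", "estimated"), names_to = "model",
                        values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$value,
                                 linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL,
                  title = paste0("operating ", object$operating,
                                 " / estimating ", object$estimating)) +
    ggplot2::theme_minimal()
}

#' Trace plots of monitored MCMC quantities
#'
#' @param object A `krill_mcmc`.
#' @param quantities Monitored quantities to show (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.krill_mcmc <- function(object, quantities = NULL, ...) {
  df <- tibble::as_tibble(object$chains) |>
    dplyr::mutate(sample = dplyr::row_number()) |>
    tidyr::pivot_longer(-"sample", names_to = "quantity",
                        values_to = "value")
  if (!is.null(quantities)) {
    df <- dplyr::filter(df, .data$quantity %in% quantities)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Saved sample", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare asymptotic and MCMC uncertainty for shared quantities
#'
#' @param intervals Output of [asymptotic_intervals()].
#' @param mcmc A `krill_mcmc` whose monitored quantities overlap
#'   `intervals$quantity`.
#' @return A tibble with both interval sets and a ggplot stored in
#'   attribute `"plot"`.
#' @export
compare_uncertainty <- function(intervals, mcmc) {
  qs <- intersect(intervals$quantity, colnames(mcmc$chains))
  mc <- purrr::map_dfr(qs, function(q) {
    x <- mcmc$chains[, q]
    tibble::tibble(quantity = q, mcmc_mean = mean(x), mcmc_sd = stats::sd(x),
                   mcmc_lower = stats::quantile(x, 0.025),
                   mcmc_upper = stats::quantile(x, 0.975))
  })
  out <- dplyr::inner_join(intervals, mc, by = "quantity")
  plt <- out |>
    ggplot2::ggplot(ggplot2::aes(y = .data$quantity)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mcmc_lower,
                                         xmax = .data$mcmc_upper),
                            height = 0.1, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate)) +
    ggplot2::labs(x = "Estimate (grey: asymptotic 95%, blue: MCMC 95%)",
                  y = NULL) +
    ggplot2::theme_minimal()
  attr(out, "plot") <- plt
  out
}
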