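# ggplot2 visualisations: trace, density and autocorrelation plots for
# chain sets, posterior curves for beta parameters, and a forest-style
# view of a report table.

#' Trace plot of retained draws
#'
#' @param chains A `chain_set` from [mcmc_sample()].
#' @return A ggplot.
#' @export
plot_trace <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  tidy(chains) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$iteration, y = .data$value,
                                 colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::labs(x = "retained iteration", y = "prevalence",
                  colour = "chain", title = "Trace of retained draws") +
    ggplot2::theme_minimal()
}

#' Per-chain posterior density plot
#'
#' @inheritParams plot_trace
#' @return A ggplot.
#' @export
plot_chain_density <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  tidy(chains) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value,
                                 colour = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "prevalence", colour = "chain",
                  title = "Per-chain posterior density") +
    ggplot2::theme_minimal()
}

#' Autocorrelation plot by chain
#'
#' @inheritParams plot_trace
#' @param max_lag Largest lag shown.
#' @return A ggplot.
#' @export
plot_acf <- function(chains, max_lag = 20) {
  stopifnot(inherits(chains, "chain_set"))
  draws <- chains$draws
  max_lag <- min(max_lag, nrow(draws) - 1L)
  purrr::map_dfr(seq_len(ncol(draws)), function(j) {
    tibble(chain = j, lag = 0:max_lag, acf = autocorr(draws[, j], max_lag))
  }) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_col(width = 0.2) +
    ggplot2::facet_wrap(~chain, labeller = ggplot2::label_both) +
    ggplot2::labs(title = "Autocorrelation of retained draws") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trace
#' @param object A `chain_set`.
#' @param ... Unused.
#' @method autoplot chain_set
#' @export
autoplot.chain_set <- function(object, ...) plot_trace(object)

#' Density curve of a beta prior or posterior
#'
#' @param object A [beta_params] object.
#' @param ... Unused.
#' @return A ggplot of the exact beta density with the equal-tailed 95%
#'   interval shaded.
#' @method autoplot beta_params
#' @export
autoplot.beta_params <- function(object, ...) {
  s <- beta_stats(object)
  grid <- tibble(x = seq(1e-4, 1 - 1e-4, length.out = 512)) |>
    dplyr::mutate(density = dbeta(.data$x, object$alpha, object$beta))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_area(data = ~dplyr::filter(.x, .data$x >= s$lower,
                                             .data$x <= s$upper),
                       fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = s$mean, linetype = 2) +
    ggplot2::labs(x = "prevalence", y = "density",
                  title = sprintf("Beta(%g, %g) [%s]", object$alpha,
                                  object$beta, object$label)) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of a report table
#'
#' @param object A `report_table` from [run_suite()].
#' @param ... Unused.
#' @return A ggplot showing each analysis's estimate and interval.
#' @method autoplot report_table
#' @export
autoplot.report_table <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$estimate)) |>
    dplyr::mutate(analysis = factor(.data$analysis,
                                    levels = rev(unique(.data$analysis))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$analysis)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper,
                                          colour = .data$interval_type)) +
    ggplot2::labs(x = "prevalence", y = NULL, colour = "interval",
                  title = "Prevalence by analysis") +
    ggplot2::theme_minimal()
}
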