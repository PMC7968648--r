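#' Trace plot of a BYM fit
#'
#' Traces of the intercept, coefficients and precisions per chain, the
#' standard first look at mixing.
#'
#' @param object A `bym_fit`.
#' @param pars Parameters to show; defaults to the fixed effects and
#'   precisions.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bym_fit <- function(object, pars = NULL, ...) {
  cols <- setdiff(names(object$draws), c("chain", "iteration"))
  if (is.null(pars)) {
    pars <- grep("^(u_|v_)", cols, value = TRUE, invert = TRUE)
  }
  long <- object$draws |>
    dplyr::select(dplyr::all_of(c("chain", "iteration", pars))) |>
    tidyr::pivot_longer(dplyr::all_of(pars), names_to = "parameter") |>
    dplyr::mutate(chain = factor(.data$chain))
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}

#' Plot posterior rate estimates with credible intervals
#'
#' Point-range display of the per-region age-standardised rates, one
#' panel per period, regions ordered by the final period's estimate.
#'
#' @param summaries Tibble from [rate_summaries()].
#' @return A ggplot.
#' @export
plot_rates <- function(summaries) {
  last_p <- utils::tail(unique(summaries$period), 1)
  ord <- summaries |>
    dplyr::filter(.data$period == last_p) |>
    dplyr::arrange(.data$mean) |>
    dplyr::pull("region")
  summaries |>
    dplyr::mutate(region = factor(.data$region, levels = ord)) |>
    ggplot2::ggplot(ggplot2::aes(.data$mean, .data$region)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::facet_wrap(~period) +
    ggplot2::labs(x = "age-standardised rate per 100,000", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-quintile rates
#'
#' @param quintile_rates Tibble from [quintile_summary()] (optionally
#'   row-bound over periods with a `period` column).
#' @return A ggplot.
#' @export
plot_quintiles <- function(quintile_rates) {
  p <- ggplot2::ggplot(quintile_rates,
                       ggplot2::aes(.data$quintile, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = "wealth quintile (Q1 poorest)",
                  y = "rate per 100,000") +
    ggplot2::theme_minimal()
  if ("period" %in% names(quintile_rates)) {
    p <- p + ggplot2::facet_wrap(~period)
  }
  p
}

#' Slope chart of rank changes between two periods
#'
#' @param ranks Tibble from [rank_regions()] covering two periods.
#' @return A ggplot.
#' @export
plot_ranks <- function(ranks) {
  periods <- unique(ranks$period)
  ranks |>
    dplyr::filter(.data$period %in% periods[c(1, length(periods))]) |>
    ggplot2::ggplot(ggplot2::aes(.data$period, .data$display_rank,
                                 group = .data$region)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse(breaks = pretty) +
    ggplot2::labs(x = NULL, y = "rank (1 = highest rate)") +
    ggplot2::theme_minimal()
}
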