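#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a fitted shift model
#'
#' One row per model parameter with posterior median, standard deviation,
#' central 95% credible bounds and split-R-hat.
#'
#' @param x A `shift_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @method tidy shift_fit
#' @export
tidy.shift_fit <- function(x, ...) {
  d <- x$draws
  tibble(
    term = colnames(d),
    estimate = apply(d, 2, median),
    std.error = apply(d, 2, sd),
    conf.low = apply(d, 2, quantile, 0.025, names = FALSE),
    conf.high = apply(d, 2, quantile, 0.975, names = FALSE),
    rhat = unname(x$rhat[colnames(d)])
  )
}

#' One-line summary of a fitted shift model
#'
#' @param x A `shift_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `nobs`, `n_years`, `chains`, `draws`,
#'   `sigma_eps`, `sigma_year` (posterior medians, km), `max_rhat`,
#'   `converged`.
#' @export
glance.shift_fit <- function(x, ...) {
  tibble(
    nobs = x$nobs,
    n_years = length(x$years),
    chains = max(x$chain),
    draws = nrow(x$draws),
    sigma_eps = median(x$draws[, "sigma_eps"]),
    sigma_year = median(x$draws[, "sigma_year"]),
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Posterior interval plot of the fixed effects
#'
#' @param object A `shift_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shift_fit
#' @export
autoplot.shift_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term %in% FIXED_TERMS, ]
  td$term <- factor(td$term, levels = rev(FIXED_TERMS))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Posterior median and 95% CRI (km northward)", y = NULL,
      title = "Fixed effects of the hierarchical shift model"
    ) +
    ggplot2::theme_minimal()
}

#' Marginal cell summaries with 66% and 95% credible intervals
#'
#' The conventional display for strategy-by-event marginal medians: thick
#' bars for the central 66% interval, thin bars for the 95%.
#'
#' @param object A `shift_cells` tibble from [marginal_medians()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shift_cells
#' @export
autoplot.shift_cells <- function(object, ...) {
  df <- as_tibble(object)
  df$event <- ifelse(df$ece, "ECE / severe year", "non-ECE year")
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$strategy, y = .data$median_km, colour = .data$event)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
      linewidth = 0.5, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$lo66, ymax = .data$hi66),
      linewidth = 1.6, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_point(
      size = 2.5, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(
      x = "Foraging strategy", y = "Distribution shift (km northward)",
      colour = NULL,
      title = "Marginal median shifts with 66%/95% credible intervals"
    ) +
    ggplot2::theme_minimal()
}

#' Map of early and late centroids per group
#'
#' Plots the early and late positional centroids of a shift table in
#' geographic coordinates, joined by arrows showing each group's
#' displacement.
#'
#' @param shifts A tibble from [shift_table()].
#' @return A ggplot.
#' @export
plot_shift_map <- function(shifts) {
  ggplot2::ggplot(shifts) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$lon_early, y = .data$lat_early,
        xend = .data$lon_late, yend = .data$lat_late,
        colour = .data$species
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(
      x = "Longitude", y = "Latitude",
      title = "Early-to-late centroid displacements"
    ) +
    ggplot2::theme_minimal()
}
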