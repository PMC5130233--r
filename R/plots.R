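# ggplot2 figures for each result type. Each plot_*/autoplot function returns
# a ggplot object the caller can theme further.

#' Plot a simulated or loaded weekly series pair
#'
#' @param object An `acfm_pair` tibble.
#' @param ... Unused.
#' @return A ggplot with the index and count series in stacked facets.
#' @method autoplot acfm_pair
#' @export
autoplot.acfm_pair <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("index_value", "deaths"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(series = factor(.data$series, c("index_value", "deaths"),
                                  c("index", "weekly counts")))
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Stacked symbol-proportion profile across lag scenarios
#'
#' One stacked bar per lag, split by the five correlation levels — the
#' at-a-glance view of where in the lag scan strong positive or negative
#' correlation concentrates.
#'
#' @param profile Output of [symbol_profile()].
#' @return A ggplot object.
#' @export
plot_symbol_profile <- function(profile) {
  long <- profile |>
    tidyr::pivot_longer(dplyr::all_of(symbol_alphabet()),
                        names_to = "symbol", values_to = "prop") |>
    dplyr::mutate(symbol = factor(.data$symbol, rev(symbol_alphabet())))
  ggplot2::ggplot(long, ggplot2::aes(.data$L, .data$prop, fill = .data$symbol)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(
      A = "#b2182b", B = "#ef8a62", C = "grey75", D = "#67a9cf", E = "#2166ac"
    )) +
    ggplot2::labs(x = "lag L (weeks)", y = "proportion of symbols",
                  fill = "level") +
    ggplot2::facet_wrap(~window, labeller = ggplot2::label_both)
}

#' Log-log degree-distribution plot with the fitted power law
#'
#' @param object A `powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$k, .data$p)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "weighted degree k", y = "P(k)",
      title = sprintf("P(k) = %.3g k^-%.3g  (R² = %.3f)",
                      object$a, object$b, object$r_squared)
    )
}

#' Node strength versus structural-hole hierarchy scatter
#'
#' Highlights transmission-medium modes: points with modest strength but high
#' hierarchy.
#'
#' @param holes Output of [structural_hole_profile()] (optionally with an
#'   `L` column to facet by).
#' @return A ggplot object.
#' @export
plot_structural_holes <- function(holes) {
  p <- ggplot2::ggplot(holes, ggplot2::aes(.data$strength, .data$hierarchy)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "node strength", y = "hierarchy H")
  if ("L" %in% names(holes)) {
    p <- p + ggplot2::facet_wrap(~L, labeller = ggplot2::label_both)
  }
  p
}

#' Shortest-path distance histogram
#'
#' @param object A `path_statistics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot path_statistics
#' @export
autoplot.path_statistics <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$distance, .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "shortest-path distance (edges)", y = "frequency",
      title = sprintf("APL = %.3f over the largest component (%d/%d nodes)",
                      object$apl, object$component_size, object$n_nodes)
    )
}

#' Periodogram plot
#'
#' @param object An `acfm_periodogram`.
#' @param ... Unused.
#' @return A ggplot object (power against period in weeks).
#' @method autoplot acfm_periodogram
#' @export
autoplot.acfm_periodogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$period, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "period (weeks)", y = "power")
}
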