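# broom-style tidy()/glance() methods for the fitted/constructed objects.

#' Tidy a mode network into its edge table
#'
#' @param x A `mode_network`.
#' @param ... Unused.
#' @return A tibble `from`, `to`, `weight`, `probability` (out-transition
#'   probability from `from`).
#' @method tidy mode_network
#' @export
tidy.mode_network <- function(x, ...) {
  transmission_probabilities(x)
}

#' One-row summary of a mode network
#'
#' @param x A `mode_network`.
#' @param ... Unused.
#' @return A tibble with `L`, `window`, `omega`, `n_nodes`, `n_edges`,
#'   `total_weight`, `n_self_loops`, `max_strength`.
#' @method glance mode_network
#' @export
glance.mode_network <- function(x, ...) {
  tibble(
    L = x$L, window = x$window, omega = x$omega,
    n_nodes = x$N, n_edges = x$E,
    total_weight = sum(x$edges$weight),
    n_self_loops = sum(x$edges$from == x$edges$to),
    max_strength = max(node_strength(x)$strength)
  )
}

#' Tidy the points behind a power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return A tibble `k`, `p` (empirical), `fitted` (`a * k^-b`).
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  dplyr::mutate(x$points, fitted = x$a * .data$k^(-x$b))
}

#' One-row summary of a power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return A tibble `a`, `b`, `r_squared`, `n_points`, `n_nodes`.
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(
    a = x$a, b = x$b, r_squared = x$r_squared,
    n_points = nrow(x$points), n_nodes = x$n_nodes
  )
}

#' Tidy a periodogram
#'
#' @param x An `acfm_periodogram`.
#' @param ... Unused.
#' @return A tibble `frequency`, `period`, `power`, `power_fraction`.
#' @method tidy acfm_periodogram
#' @export
tidy.acfm_periodogram <- function(x, ...) {
  tibble(
    frequency = x$frequency,
    period = x$period,
    power = x$power,
    power_fraction = x$power / sum(x$power)
  )
}

#' One-row summary of a periodogram
#'
#' @param x An `acfm_periodogram`.
#' @param ... Unused.
#' @return A tibble `n`, `dominant_period`, `dominant_power_fraction`, `flat`.
#' @method glance acfm_periodogram
#' @export
glance.acfm_periodogram <- function(x, ...) {
  tibble(
    n = x$n,
    dominant_period = x$dominant_period,
    dominant_power_fraction = x$dominant_power_fraction,
    flat = x$flat
  )
}

#' Tidy path statistics into the distance histogram
#'
#' @param x A `path_statistics` object.
#' @param ... Unused.
#' @return The histogram tibble (`distance`, `n_pairs`, `frequency`).
#' @method tidy path_statistics
#' @export
tidy.path_statistics <- function(x, ...) {
  x$histogram
}

#' One-row summary of path statistics
#'
#' @param x A `path_statistics` object.
#' @param ... Unused.
#' @return A tibble `apl`, `diameter`, `n_nodes`, `component_size`,
#'   `coverage`.
#' @method glance path_statistics
#' @export
glance.path_statistics <- function(x, ...) {
  tibble(
    apl = x$apl, diameter = x$diameter, n_nodes = x$n_nodes,
    component_size = x$component_size, coverage = x$coverage
  )
}
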