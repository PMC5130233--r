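#' Build a directed weighted fluctuation-mode transition network
#'
#' Turns a fluctuation-mode sequence into a directed weighted graph: each
#' distinct mode becomes a node and every consecutive pair
#' `modes[i] -> modes[i + 1]` adds one unit of weight to the corresponding
#' directed edge. Repeated transitions accumulate weight and self-loops are
#' kept (a mode following itself), so the total edge weight always equals
#' `length(modes) - 1`.
#'
#' @param modes Character vector of modes (length `>= 2`), e.g. one
#'   scenario's `mode` column from [mode_sequences()].
#' @param L,window,omega Optional metadata recorded on the network.
#' @return An object of class `mode_network`: a list with the igraph `graph`,
#'   an `edges` tibble (`from`, `to`, `weight`), node count `N`, edge count
#'   `E`, and the metadata.
#' @export
#' @examples
#' net <- build_mode_network(c("CDB", "DBD", "BDB", "DBD", "DBD"))
#' net$N
#' net$edges
build_mode_network <- function(modes, L = NA_integer_, window = NA_integer_,
                               omega = NA_integer_) {
  if (length(modes) < 2L) {
    abort("need at least 2 modes to form a transition.")
  }
  edges <- tibble(from = modes[-length(modes)], to = modes[-1L]) |>
    dplyr::count(.data$from, .data$to, name = "weight") |>
    dplyr::arrange(.data$from, .data$to)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = sort(unique(modes))
  )
  structure(
    list(
      graph = g,
      edges = edges,
      N = igraph::vcount(g),
      E = igraph::ecount(g),
      n_modes = length(modes),
      L = L, window = window, omega = omega
    ),
    class = "mode_network"
  )
}

#' @export
print.mode_network <- function(x, ...) {
  cat(sprintf(
    "<mode_network> N = %d nodes, E = %d edges, total weight = %d%s\n",
    x$N, x$E, sum(x$edges$weight),
    if (is.na(x$L)) "" else sprintf(" (L = %d, T = %d, omega = %d)", x$L, x$window, x$omega)
  ))
  invisible(x)
}

#' Build one network per selected scenario
#'
#' @param modes_tbl Mode table from [mode_sequences()].
#' @param lags Which lags to build networks for (default: all present).
#' @return A tibble with columns `L`, `window`, `omega`, and a list-column
#'   `network` of `mode_network` objects.
#' @export
build_mode_networks <- function(modes_tbl, lags = NULL) {
  if (!is.null(lags)) {
    modes_tbl <- dplyr::filter(modes_tbl, .data$L %in% lags)
  }
  modes_tbl |>
    dplyr::arrange(.data$L, .data$window, .data$position) |>
    dplyr::reframe(
      network = list(build_mode_network(
        .data$mode,
        L = .data$L[1], window = .data$window[1], omega = .data$omega[1]
      )),
      .by = c("L", "window", "omega")
    )
}

#' Node strength (weighted degree)
#'
#' The strength of a mode is the total weight of all edges attached to it:
#' in-strength plus out-strength, a self-loop counting once in each (so
#' twice in total, preserving the handshake identity
#' `sum(strength) = 2 * sum(weights)`). High-strength modes are the key
#' fluctuation patterns through which the correlation dynamics flow.
#'
#' @param net A [build_mode_network()] object.
#' @param node Optional single mode string; if given, returns its strength as
#'   a number (unknown modes are an error).
#' @return A tibble (`mode`, `in_strength`, `out_strength`, `strength`)
#'   sorted by mode, or a single number when `node` is given.
#' @export
node_strength <- function(net, node = NULL) {
  stopifnot(inherits(net, "mode_network"))
  modes <- igraph::V(net$graph)$name
  ins <- igraph::strength(net$graph, mode = "in", loops = TRUE)
  outs <- igraph::strength(net$graph, mode = "out", loops = TRUE)
  tbl <- tibble(
    mode = modes,
    in_strength = as.numeric(ins),
    out_strength = as.numeric(outs),
    strength = as.numeric(ins + outs)
  ) |>
    dplyr::arrange(.data$mode)
  if (is.null(node)) {
    return(tbl)
  }
  hit <- match(node, tbl$mode)
  if (is.na(hit)) {
    abort(sprintf("mode '%s' is not a node of this network.", node))
  }
  tbl$strength[hit]
}

#' Transition probabilities out of each mode
#'
#' Normalizes each node's out-edge weights to sum to one — the maximum
#' likelihood estimate of the Markov transition probabilities of the mode
#' sequence, usable to anticipate the next fluctuation pattern.
#'
#' @inheritParams node_strength
#' @param node Optional single mode; restricts the output to that mode's
#'   out-transitions (a sink mode yields an empty table with a warning).
#' @return A tibble with columns `from`, `to`, `weight`, `probability`.
#' @export
transmission_probabilities <- function(net, node = NULL) {
  stopifnot(inherits(net, "mode_network"))
  probs <- net$edges |>
    dplyr::mutate(probability = .data$weight / sum(.data$weight), .by = "from")
  if (is.null(node)) {
    return(probs)
  }
  if (!node %in% igraph::V(net$graph)$name) {
    abort(sprintf("mode '%s' is not a node of this network.", node))
  }
  out <- dplyr::filter(probs, .data$from == node)
  if (nrow(out) == 0L) {
    warn(sprintf("mode '%s' is a sink (no out-transitions).", node))
  }
  out
}

#' Key fluctuation modes by node strength
#'
#' Ranks modes by strength (descending, ties broken lexicographically on the
#' mode string) and reports each mode's share — strength over total strength —
#' and the cumulative share, showing how much of the transition mass the top
#' modes carry.
#'
#' @inheritParams node_strength
#' @param top_k Number of modes to keep (default all).
#' @return A tibble `rank`, `mode`, `strength`, `share`, `cumulative_share`.
#' @export
key_modes <- function(net, top_k = NULL) {
  tbl <- node_strength(net) |>
    dplyr::arrange(dplyr::desc(.data$strength), .data$mode) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      share = .data$strength / sum(.data$strength),
      cumulative_share = cumsum(.data$share),
      .before = 1
    ) |>
    dplyr::select("rank", "mode", "strength", "share", "cumulative_share")
  if (!is.null(top_k)) {
    tbl <- dplyr::slice_head(tbl, n = top_k)
  }
  tbl
}

#' Fit a power law to the weighted-degree distribution
#'
#' Computes the empirical probability mass `P(k)` = fraction of nodes whose
#' weighted degree (node strength, in + out) equals `k`, then fits
#' `P(k) = a * k^-b` by ordinary least squares on
#' `(log10 k, log10 P(k))` over the distinct observed positive degrees. A
#' heavy-tailed, approximately linear log-log relationship (high R-squared,
#' exponent typically 2-3 for these transition networks) is the scale-free
#' signature: most modes are rare while a few dominate the dynamics.
#'
#' @param x A `mode_network`, or a numeric vector of (weighted) degrees.
#' @param ... Unused.
#' @return An object of class `powerlaw_fit`: list with `a`, `b`,
#'   `r_squared`, the `points` tibble (`k`, `p`), and `n_nodes`.
#' @export
#' @examples
#' set.seed(1)
#' k <- sample(1:20, 400, replace = TRUE, prob = (1:20)^-2)
#' fit_power_law(k)
fit_power_law <- function(x, ...) {
  UseMethod("fit_power_law")
}

#' @rdname fit_power_law
#' @export
fit_power_law.mode_network <- function(x, ...) {
  fit_power_law(node_strength(x)$strength, ...)
}

#' @rdname fit_power_law
#' @export
fit_power_law.numeric <- function(x, ...) {
  if (any(x < 0)) {
    abort("degrees must be nonnegative.")
  }
  n <- length(x)
  tab <- table(x[x > 0])
  points <- tibble(
    k = as.numeric(names(tab)),
    p = as.numeric(tab) / n
  )
  if (nrow(points) < 3L) {
    abort(sprintf(
      "power-law fit needs >= 3 distinct positive degrees (got %d).",
      nrow(points)
    ))
  }
  fit <- lm(log10(p) ~ log10(k), data = points)
  structure(
    list(
      a = 10^coef(fit)[[1]],
      b = -coef(fit)[[2]],
      r_squared = summary(fit)$r.squared,
      points = points,
      n_nodes = n
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> P(k) = %.4g * k^-%.4g  (R^2 = %.3f, %d distinct degrees)\n",
    x$a, x$b, x$r_squared, nrow(x$points)
  ))
  invisible(x)
}

#' Undirected weighted projection of a mode network
#'
#' Collapses each pair of opposite directed edges into one undirected edge
#' whose weight is the sum of the two directed weights, and drops self-loops.
#' The cohesion, structural-hole and path statistics are all computed on this
#' projection.
#'
#' @inheritParams node_strength
#' @return An undirected weighted simple igraph graph.
#' @export
undirected_projection <- function(net) {
  stopifnot(inherits(net, "mode_network"))
  g <- igraph::as_undirected(net$graph, mode = "collapse",
                             edge.attr.comb = list(weight = "sum"))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "sum"))
}

#' Export a mode network
#'
#' @inheritParams node_strength
#' @param graphml_path,edgelist_path Output paths (either may be `NULL` to
#'   skip that format). The edge list is a CSV `source,target,weight`.
#' @return The network, invisibly.
#' @export
write_mode_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  stopifnot(inherits(net, "mode_network"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    readr::write_csv(
      dplyr::rename(net$edges, source = "from", target = "to"),
      edgelist_path
    )
  }
  invisible(net)
}
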