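# Cohesive-subgroup, structural-hole and path statistics, all computed on the
# simple undirected projection of the directed mode network (edge weight =
# sum of the two directed weights, self-loops dropped).

as_projection <- function(net) {
  if (inherits(net, "mode_network")) {
    return(undirected_projection(net))
  }
  if (inherits(net, "igraph")) {
    if (igraph::is_directed(net)) {
      abort("expected an undirected graph or a mode_network.")
    }
    return(igraph::simplify(net, edge.attr.comb = list(weight = "sum")))
  }
  abort("`net` must be a mode_network or an igraph graph.")
}

proj_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(1, igraph::ecount(g))
  }
}

node_index <- function(g, node) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    return(check_scalar_int(node, "node", min = 1))
  }
  hit <- match(node, nm)
  if (is.na(hit)) {
    abort(sprintf("node '%s' is not in the network.", node))
  }
  hit
}

#' Local clustering coefficient
#'
#' `CC_i = E_i / (k_i (k_i - 1) / 2)` where `k_i` is the number of neighbors
#' of `i` in the unweighted undirected projection and `E_i` the number of
#' edges among those neighbors. Nodes with fewer than 2 neighbors have no
#' possible neighbor pair and get `CC = 0` by convention.
#'
#' @param net A `mode_network` or an undirected igraph graph.
#' @param node Optional node name; if given, returns the single value.
#' @return A tibble (`mode`, `k`, `cc`) or a single number.
#' @export
clustering_coefficient <- function(net, node = NULL) {
  g <- as_projection(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  cc[deg < 2] <- 0
  tbl <- tibble(
    mode = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    k = as.integer(deg),
    cc = as.numeric(cc)
  )
  if (is.null(node)) {
    return(tbl)
  }
  tbl$cc[node_index(g, node)]
}

#' Enumerate k-plex cohesive subgroups
#'
#' Exhaustively enumerates node subsets of size `g` of the undirected
#' projection in which every member is adjacent to at least `g - sigma` other
#' members (a k-plex, a relaxation of a clique; a complete subgraph always
#' qualifies). Each qualifying subgroup is scored by its total internal edge
#' weight, labelled with its majority correlation category
#' (see [subgroup_category()]), and assigned a core mode — the member with
#' the highest clustering coefficient in the full network (ties broken
#' lexicographically).
#'
#' @param net A `mode_network` or undirected igraph graph.
#' @param g_size Subgroup size `g` (default 3).
#' @param sigma Adjacency relaxation (default 2); must satisfy
#'   `1 <= sigma < g_size`.
#' @param top_k How many top-weight subgroups to return (default 6;
#'   `Inf` for all). Ties are broken lexicographically on the member list.
#' @return A tibble with one row per subgroup: `rank`, `members`
#'   (list-column, sorted), `internal_weight`, `member_cc` (list-column),
#'   `core_mode`, `category`.
#' @export
#' @examples
#' net <- build_mode_network(c("AAA", "AAB", "ABB", "AAA", "AAB", "AAA"))
#' enumerate_kplex(net, g_size = 3, sigma = 2)
enumerate_kplex <- function(net, g_size = 3L, sigma = 2L, top_k = 6L) {
  check_scalar_int(g_size, "g_size", min = 2)
  check_scalar_int(sigma, "sigma", min = 1)
  if (sigma >= g_size) {
    abort("`sigma` must be smaller than `g_size`.")
  }
  gr <- as_projection(net)
  n <- igraph::vcount(gr)
  if (g_size > n) {
    warn(sprintf("subgroup size %d exceeds the %d network nodes.", g_size, n))
    return(empty_subgroup_tbl())
  }
  nm <- igraph::V(gr)$name %||% as.character(seq_len(n))
  adj <- igraph::as_adjacency_matrix(gr, sparse = FALSE) > 0
  wadj <- igraph::as_adjacency_matrix(gr, attr = if ("weight" %in%
    igraph::edge_attr_names(gr)) "weight" else NULL, sparse = FALSE)
  cc_tbl <- clustering_coefficient(net)
  cc_lookup <- setNames(cc_tbl$cc, cc_tbl$mode)
  keep <- kplex_candidates(adj, g_size, sigma)
  if (length(keep) == 0L) {
    return(empty_subgroup_tbl())
  }
  rows <- purrr::map_dfr(keep, function(idx) {
    members <- sort(nm[idx])
    w <- sum(wadj[idx, idx]) / 2
    ccs <- unname(cc_lookup[members])
    core <- members[order(-ccs, members)][1]
    tibble(
      members = list(members),
      internal_weight = w,
      member_cc = list(setNames(ccs, members)),
      core_mode = core,
      category = subgroup_category(members)
    )
  })
  rows |>
    dplyr::mutate(member_key = purrr::map_chr(.data$members, paste, collapse = ",")) |>
    dplyr::arrange(dplyr::desc(.data$internal_weight), .data$member_key) |>
    dplyr::select(-"member_key") |>
    dplyr::slice_head(n = if (is.finite(top_k)) top_k else nrow(rows)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

# Qualifying subsets of size g (every member with >= g - sigma internal
# links). For the default g = 3 a qualifying triple always contains a
# "center" adjacent to both other members, so enumerating neighbor pairs of
# each node visits all candidates far faster than scanning all n-choose-3
# subsets; larger g falls back to exhaustive enumeration.
kplex_candidates <- function(adj, g_size, sigma) {
  n <- nrow(adj)
  ok <- function(idx) {
    sub <- adj[idx, idx, drop = FALSE]
    all(rowSums(sub) >= g_size - sigma)
  }
  if (g_size == 3L) {
    seen <- new.env(hash = TRUE)
    out <- list()
    for (v in seq_len(n)) {
      nbrs <- which(adj[v, ])
      if (length(nbrs) < 2L) next
      pairs <- combn(nbrs, 2L)
      for (p in seq_len(ncol(pairs))) {
        idx <- sort(c(v, pairs[1, p], pairs[2, p]))
        key <- paste(idx, collapse = ".")
        if (is.null(seen[[key]]) && ok(idx)) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- idx
        } else {
          seen[[key]] <- TRUE
        }
      }
    }
    return(out)
  }
  purrr::keep(combn(n, g_size, simplify = FALSE), ok)
}

empty_subgroup_tbl <- function() {
  tibble(
    rank = integer(), members = list(), internal_weight = numeric(),
    member_cc = list(), core_mode = character(), category = character()
  )
}

#' Correlation category of a subgroup
#'
#' Tallies the five correlation letters over all symbols of all member mode
#' strings and maps the majority letter to its category: A = strong positive,
#' B = weak positive, C = no, D = weak negative, E = strong negative
#' correlation. Ties go to the weaker category (the one closer to "no
#' correlation"; an exact positive/negative tie at equal level, e.g. B vs D,
#' falls back to the positive letter, which sorts first).
#'
#' @param members Character vector of member mode strings.
#' @return A single label such as `"weak negative correlation"`.
#' @export
#' @examples
#' subgroup_category(c("EEE", "EEB", "BEE"))
subgroup_category <- function(members) {
  if (length(members) == 0L) {
    abort("`members` must be nonempty.")
  }
  letters5 <- symbol_alphabet()
  tally <- table(factor(strsplit(paste(members, collapse = ""), "")[[1]],
                        levels = letters5))
  strength <- c(A = 2, B = 1, C = 0, D = 1, E = 2)
  winners <- letters5[tally == max(tally)]
  pick <- winners[order(strength[winners], winners)][1]
  paste(symbol_labels()[[pick]], "correlation")
}

# Row-normalized tie proportions p_ij of the weighted undirected projection.
tie_proportions <- function(g) {
  w <- igraph::as_adjacency_matrix(
    g,
    attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = FALSE
  )
  rs <- rowSums(w)
  p <- w / ifelse(rs == 0, 1, rs)
  dimnames(p) <- list(igraph::V(g)$name, igraph::V(g)$name)
  p
}

#' Burt constraint of a node on one neighbor
#'
#' `C_ij = (p_ij + sum_q p_iq p_qj)^2`, where `p_ij` is node `i`'s
#' proportional tie strength to `j` (projected edge weight over `i`'s total
#' weight) and `q` runs over `i`'s other contacts. High constraint means `i`'s
#' relationship with `j` is reinforced by shared contacts — `i` spans no
#' structural hole there; low constraint marks `i` as a bridge.
#'
#' @param net A `mode_network` or undirected igraph graph.
#' @param i Node name (or index for unnamed graphs).
#' @param j Neighbor of `i`; if `NULL`, constraints on all neighbors are
#'   returned.
#' @return A tibble (`i`, `j`, `p_ij`, `constraint`), or a single number when
#'   `j` is given.
#' @export
#' @examples
#' g <- igraph::make_star(5, mode = "undirected", center = 1)
#' igraph::V(g)$name <- c("hub", "a", "b", "c", "d")
#' constraint(g, "hub", "a") # 1/16: no indirect reinforcement
constraint <- function(net, i, j = NULL) {
  g <- as_projection(net)
  p <- tie_proportions(g)
  ii <- node_index(g, i)
  nbrs <- which(p[ii, ] > 0)
  if (length(nbrs) == 0L) {
    abort(sprintf("node '%s' is isolated; constraint is undefined.", i))
  }
  c_row <- vapply(nbrs, function(jj) {
    q <- setdiff(nbrs, jj)
    (p[ii, jj] + sum(p[ii, q] * p[q, jj]))^2
  }, numeric(1))
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  tbl <- tibble(
    i = nm[ii], j = nm[nbrs],
    p_ij = unname(p[ii, nbrs]),
    constraint = unname(c_row)
  )
  if (is.null(j)) {
    return(tbl)
  }
  hit <- match(if (is.character(j)) j else nm[j], tbl$j)
  if (is.na(hit)) {
    abort(sprintf("'%s' is not a neighbor of '%s'.", j, i))
  }
  tbl$constraint[hit]
}

#' Coleman-Theil hierarchy of a node's constraint distribution
#'
#' `H_i = sum_j (C_ij / Cbar) ln(C_ij / Cbar) / (N ln N)` where `Cbar` is the
#' mean constraint over `i`'s neighbors and `N` the ego-network size (`i`
#' plus its neighbors). `H_i = 0` when constraint is spread evenly over the
#' neighbors and grows as it concentrates on a few of them; it is always
#' nonnegative. Nodes with fewer than 2 neighbors get `H_i = 0` by
#' convention.
#'
#' @inheritParams constraint
#' @param node Optional node name for a single value.
#' @return A tibble (`mode`, `n_neighbors`, `hierarchy`) or a single number.
#' @export
hierarchy <- function(net, node = NULL) {
  g <- as_projection(net)
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  one <- function(v) {
    deg <- igraph::degree(g, v)
    if (deg < 2) {
      return(0)
    }
    c_ij <- constraint(g, nm[v])$constraint
    cbar <- mean(c_ij)
    ratio <- c_ij / cbar
    n_ego <- deg + 1
    sum(ratio * log(ratio)) / (n_ego * log(n_ego))
  }
  vals <- vapply(seq_len(igraph::vcount(g)), one, numeric(1))
  tbl <- tibble(
    mode = nm,
    n_neighbors = as.integer(igraph::degree(g)),
    hierarchy = vals
  )
  if (is.null(node)) {
    return(tbl)
  }
  tbl$hierarchy[node_index(g, node)]
}

#' Structural-hole profile of every mode
#'
#' Joins node strength, aggregate constraint and hierarchy per node — the
#' data behind a strength-versus-hierarchy scatter, which singles out
#' transmission-medium modes: modest strength but high hierarchy, bridging
#' otherwise separate parts of the fluctuation dynamics.
#'
#' @param net A `mode_network`.
#' @return A tibble (`mode`, `strength`, `n_neighbors`, `total_constraint`,
#'   `hierarchy`).
#' @export
structural_hole_profile <- function(net) {
  stopifnot(inherits(net, "mode_network"))
  g <- undirected_projection(net)
  nm <- igraph::V(g)$name
  total_c <- vapply(nm, function(v) {
    if (igraph::degree(g, v) == 0) {
      return(NA_real_)
    }
    sum(constraint(g, v)$constraint)
  }, numeric(1))
  node_strength(net) |>
    dplyr::select("mode", "strength") |>
    dplyr::left_join(hierarchy(net), by = "mode") |>
    dplyr::mutate(total_constraint = unname(total_c[.data$mode])) |>
    dplyr::select("mode", "strength", "n_neighbors", "total_constraint",
                  "hierarchy")
}

#' Shortest-path statistics
#'
#' Unweighted shortest-path lengths between all unordered node pairs of the
#' largest connected component of the undirected projection. Returns the
#' distance histogram and the average path length (APL), the mean over those
#' pairs; restricting to the largest component keeps the APL finite, with the
#' covered node fraction reported alongside.
#'
#' @param net A `mode_network` or undirected igraph graph.
#' @return A list of class `path_statistics`: `histogram` (tibble `distance`,
#'   `n_pairs`, `frequency`), `apl` (`NA` for a singleton component),
#'   `diameter`, `n_nodes`, `component_size`, `coverage`.
#' @export
path_statistics <- function(net) {
  g <- as_projection(net)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  n_sub <- igraph::vcount(sub)
  if (n_sub < 2L) {
    return(structure(
      list(
        histogram = tibble(distance = integer(), n_pairs = integer(),
                           frequency = numeric()),
        apl = NA_real_, diameter = NA_integer_,
        n_nodes = igraph::vcount(g), component_size = n_sub,
        coverage = n_sub / max(igraph::vcount(g), 1L)
      ),
      class = "path_statistics"
    ))
  }
  d <- igraph::distances(sub, weights = NA)
  dd <- d[upper.tri(d)]
  hist_tbl <- tibble(distance = as.integer(dd)) |>
    dplyr::count(.data$distance, name = "n_pairs") |>
    dplyr::mutate(frequency = .data$n_pairs / sum(.data$n_pairs))
  structure(
    list(
      histogram = hist_tbl,
      apl = mean(dd),
      diameter = as.integer(max(dd)),
      n_nodes = igraph::vcount(g),
      component_size = n_sub,
      coverage = n_sub / igraph::vcount(g)
    ),
    class = "path_statistics"
  )
}

#' @export
print.path_statistics <- function(x, ...) {
  cat(sprintf(
    "<path_statistics> APL = %.3f, diameter = %s, largest component %d/%d nodes (%.0f%%)\n",
    x$apl, format(x$diameter), x$component_size, x$n_nodes, 100 * x$coverage
  ))
  invisible(x)
}
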