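# Independent brute-force oracles. Deliberately naive (explicit loops,
# term-by-term summation) so they share no code path with the package.

oracle_pearson <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  num <- 0
  dx <- 0
  dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xbar) * (y[i] - ybar)
    dx <- dx + (x[i] - xbar)^2
    dy <- dy + (y[i] - ybar)^2
  }
  if (dx == 0 || dy == 0) {
    return(NA_real_)
  }
  num / sqrt(dx * dy)
}

# adj: symmetric 0/1 matrix without self-links.
oracle_cc <- function(adj, i) {
  nbrs <- which(adj[i, ] > 0)
  k <- length(nbrs)
  if (k < 2) {
    return(0)
  }
  e <- 0
  for (a in seq_along(nbrs)) {
    for (b in seq_along(nbrs)) {
      if (a < b && adj[nbrs[a], nbrs[b]] > 0) {
        e <- e + 1
      }
    }
  }
  e / (k * (k - 1) / 2)
}

# w: symmetric weight matrix, zero diagonal.
oracle_constraint <- function(w, i, j) {
  n <- nrow(w)
  p <- matrix(0, n, n)
  for (a in seq_len(n)) {
    tot <- sum(w[a, ])
    if (tot > 0) {
      for (b in seq_len(n)) p[a, b] <- w[a, b] / tot
    }
  }
  indirect <- 0
  for (q in seq_len(n)) {
    if (q != i && q != j && w[i, q] > 0) {
      indirect <- indirect + p[i, q] * p[q, j]
    }
  }
  (p[i, j] + indirect)^2
}

oracle_hierarchy <- function(w, i) {
  nbrs <- which(w[i, ] > 0)
  if (length(nbrs) < 2) {
    return(0)
  }
  cvals <- vapply(nbrs, function(j) oracle_constraint(w, i, j), numeric(1))
  cbar <- mean(cvals)
  n_ego <- length(nbrs) + 1
  total <- 0
  for (cv in cvals) {
    total <- total + (cv / cbar) * log(cv / cbar)
  }
  total / (n_ego * log(n_ego))
}

oracle_bfs_distances <- function(adj, from) {
  n <- nrow(adj)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in which(adj[v, ] > 0)) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  dist
}

oracle_apl <- function(adj) {
  n <- nrow(adj)
  # largest component by repeated BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      comp[!is.na(oracle_bfs_distances(adj, v))] <- cid
    }
  }
  members <- which(comp == which.max(tabulate(comp)))
  dd <- c()
  for (a in members) {
    d <- oracle_bfs_distances(adj, a)
    for (b in members) {
      if (b > a) {
        dd <- c(dd, d[b])
      }
    }
  }
  if (length(dd) == 0) {
    return(NA_real_)
  }
  mean(dd)
}

# All size-g subsets in which every member keeps >= g - sigma internal links.
oracle_kplex_triples <- function(adj, g = 3, sigma = 2) {
  n <- nrow(adj)
  if (n < g) {
    return(list())
  }
  out <- list()
  for (combo in utils::combn(n, g, simplify = FALSE)) {
    ok <- TRUE
    for (v in combo) {
      links <- 0
      for (u in combo) {
        if (u != v && adj[v, u] > 0) {
          links <- links + 1
        }
      }
      if (links < g - sigma) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      out[[length(out) + 1]] <- combo
    }
  }
  out
}

# Random symmetric weighted graph helpers (no igraph, to stay independent).
random_weight_matrix <- function(n, p_edge = 0.4, max_w = 5L) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w[i, j] <- w[j, i] <- sample.int(max_w, 1)
      }
    }
  }
  w
}

graph_from_weights <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- as.character(seq_len(nrow(w)))
  g
}

random_mode_seq <- function(len, n_letters = 3, omega = 2) {
  letters_pool <- c("A", "B", "C", "D", "E")[seq_len(n_letters)]
  syms <- sample(letters_pool, len + omega - 1, replace = TRUE)
  acfmnet::coarse_grain(syms, omega = omega)
}
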