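triangle_graph <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 1
  w
}

path3_graph <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w
}

test_that("clustering coefficients match neighbor-pair enumeration", {
  tri <- graph_from_weights(triangle_graph())
  expect_equal(clustering_coefficient(tri)$cc, c(1, 1, 1))
  path <- graph_from_weights(path3_graph())
  expect_equal(clustering_coefficient(path, "2"), 0)
  expect_equal(clustering_coefficient(path)$cc, c(0, 0, 0)) # k < 2 -> 0

  withr::with_seed(61, {
    for (i in 1:100) {
      w <- random_weight_matrix(12, p_edge = stats::runif(1, 0.15, 0.6))
      g <- graph_from_weights(w)
      got <- clustering_coefficient(g)$cc
      want <- vapply(1:12, function(v) oracle_cc(w > 0, v), numeric(1))
      expect_equal(got, want)
    }
  })
  expect_error(clustering_coefficient(tri, "9"), "not in the network")
})

test_that("k-plex enumeration equals the naive all-triples filter", {
  # a triangle qualifies; a 3-path qualifies (each node >= g - sigma = 1 link)
  expect_equal(nrow(enumerate_kplex(graph_from_weights(triangle_graph()),
                                    3, 2, top_k = Inf)), 1)
  expect_equal(nrow(enumerate_kplex(graph_from_weights(path3_graph()),
                                    3, 2, top_k = Inf)), 1)
  # a single edge plus an isolated third node does not
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  expect_equal(nrow(enumerate_kplex(graph_from_weights(w), 3, 2, top_k = Inf)), 0)

  withr::with_seed(67, {
    sizes <- c(sample(5:25, 18, replace = TRUE), 60)
    for (n in sizes) {
      w <- random_weight_matrix(n, p_edge = stats::runif(1, 0.05, 0.3))
      g <- graph_from_weights(w)
      got <- enumerate_kplex(g, 3, 2, top_k = Inf)
      want <- oracle_kplex_triples(w > 0, 3, 2)
      expect_equal(nrow(got), length(want))
      if (length(want) > 0) {
        got_sets <- sort(vapply(got$members, paste, "", collapse = ","))
        want_sets <- sort(vapply(want, function(s) {
          paste(sort(as.character(s)), collapse = ",")
        }, ""))
        expect_equal(got_sets, want_sets)
      }
    }
  })
})

test_that("subgroup categories follow the majority letter with weak tie-breaks", {
  expect_equal(subgroup_category(c("EEE", "EEB", "BEE")),
               "strong negative correlation")
  expect_equal(subgroup_category(c("CCC", "DCC", "CCE")), "no correlation")
  expect_equal(subgroup_category("AAA"), "strong positive correlation")
  # tie between A (strong) and B (weak): the weaker label wins
  expect_equal(subgroup_category(c("AAA", "BBB")), "weak positive correlation")
  # tie between B and C: no correlation is the weaker
  expect_equal(subgroup_category(c("BBB", "CCC")), "no correlation")
})

test_that("subgroups carry their highest-clustering member as core mode", {
  modes <- c("AAB", "ABB", "BBA", "AAB", "ABB", "AAB", "BBA", "AAB")
  net <- build_mode_network(modes)
  subs <- enumerate_kplex(net, 3, 2, top_k = Inf)
  expect_gt(nrow(subs), 0)
  cc <- clustering_coefficient(net)
  for (r in seq_len(nrow(subs))) {
    ccs <- cc$cc[match(subs$members[[r]], cc$mode)]
    best <- subs$members[[r]][order(-ccs, subs$members[[r]])][1]
    expect_equal(subs$core_mode[r], best)
  }
})

test_that("constraint matches the closed forms and a triple-loop oracle", {
  # dyad: p_ij = 1 so C_ij = 1
  w2 <- matrix(0, 2, 2)
  w2[1, 2] <- w2[2, 1] <- 3
  expect_equal(constraint(graph_from_weights(w2), "1", "2"), 1)

  # star center with m leaves, unit weights: C = 1/m^2, no indirect paths
  for (m in c(3, 5)) {
    w <- matrix(0, m + 1, m + 1)
    w[1, 2:(m + 1)] <- w[2:(m + 1), 1] <- 1
    g <- graph_from_weights(w)
    expect_equal(constraint(g, "1", "2"), 1 / m^2)
  }

  withr::with_seed(71, {
    for (i in 1:100) {
      n <- sample(4:10, 1)
      w <- random_weight_matrix(n, p_edge = 0.5)
      if (all(rowSums(w) > 0)) {
        g <- graph_from_weights(w)
        i0 <- sample(n, 1)
        tbl <- constraint(g, as.character(i0))
        expect_equal(sum(tbl$p_ij), 1, tolerance = 1e-12)
        for (r in seq_len(nrow(tbl))) {
          expect_equal(
            tbl$constraint[r],
            oracle_constraint(w, i0, as.integer(tbl$j[r])),
            tolerance = 1e-12
          )
        }
      }
    }
  })
})

test_that("removing an indirect tie never increases constraint", {
  w <- triangle_graph() # i-j reinforced through q
  with_q <- constraint(graph_from_weights(w), "1", "2")
  w_cut <- w
  w_cut[3, 2] <- w_cut[2, 3] <- 0 # cut the q-j tie
  without_q <- constraint(graph_from_weights(w_cut), "1", "2")
  expect_lt(without_q, with_q)
})

test_that("hierarchy matches direct formula evaluation and is nonnegative", {
  # equal constraints -> 0 (star center)
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- w[2:5, 1] <- 1
  expect_equal(hierarchy(graph_from_weights(w), "1"), 0)

  withr::with_seed(73, {
    for (i in 1:100) {
      n <- sample(4:9, 1)
      w <- random_weight_matrix(n, p_edge = 0.55)
      g <- graph_from_weights(w)
      tbl <- hierarchy(g)
      for (v in seq_len(n)) {
        expect_equal(tbl$hierarchy[v], oracle_hierarchy(w, v),
                     tolerance = 1e-12)
        expect_gte(tbl$hierarchy[v], -1e-12)
      }
    }
  })
})

test_that("path statistics equal a BFS oracle on the largest component", {
  p3 <- path_statistics(graph_from_weights(path3_graph()))
  expect_equal(p3$apl, 4 / 3)
  expect_equal(sort(p3$histogram$distance), c(1, 2))
  expect_equal(p3$histogram$n_pairs[p3$histogram$distance == 1], 2)

  k5 <- matrix(1, 5, 5)
  diag(k5) <- 0
  expect_equal(path_statistics(graph_from_weights(k5))$apl, 1)

  withr::with_seed(79, {
    for (i in 1:100) {
      w <- random_weight_matrix(15, p_edge = stats::runif(1, 0.08, 0.35))
      stats_got <- path_statistics(graph_from_weights(w))
      expect_equal(stats_got$apl, oracle_apl(w > 0))
      expect_equal(sum(stats_got$histogram$n_pairs),
                   choose(stats_got$component_size, 2))
    }
  })
})

test_that("structural-hole profiles join strength, constraint and hierarchy", {
  net <- build_mode_network(
    c("AAB", "ABB", "AAB", "BBA", "ABB", "AAB", "BBA", "AAB", "ABB")
  )
  prof <- structural_hole_profile(net)
  expect_equal(sort(prof$mode), sort(node_strength(net)$mode))
  expect_true(all(prof$hierarchy >= -1e-12, na.rm = TRUE))
  expect_equal(prof$strength, node_strength(net)$strength[
    match(prof$mode, node_strength(net)$mode)
  ])
})
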