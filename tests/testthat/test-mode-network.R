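test_that("transition networks are built from consecutive mode pairs", {
  net <- build_mode_network(c("AAA", "AAA", "AAA"))
  expect_equal(net$N, 1)
  expect_equal(net$E, 1)
  expect_equal(net$edges$weight, 2) # one self-loop of weight 2

  net2 <- build_mode_network(c("X", "Y", "X", "Y"))
  expect_equal(net2$N, 2)
  e <- net2$edges
  expect_equal(e$weight[e$from == "X" & e$to == "Y"], 2)
  expect_equal(e$weight[e$from == "Y" & e$to == "X"], 1)

  expect_error(build_mode_network("AAA"), "at least 2")
})

test_that("edge multiset round-trips to the consecutive-pair multiset", {
  withr::with_seed(41, {
    for (i in 1:30) {
      modes <- random_mode_seq(sample(10:60, 1))
      net <- build_mode_network(modes)
      expect_equal(sum(net$edges$weight), length(modes) - 1)
      regenerated <- net$edges[rep(seq_len(nrow(net$edges)), net$edges$weight), ]
      got <- sort(paste(regenerated$from, regenerated$to))
      want <- sort(paste(modes[-length(modes)], modes[-1]))
      expect_equal(got, want)
    }
  })
})

test_that("node strength sums in- and out-weights with self-loops counted twice", {
  # node 'b': in-edges 2 + 3, out-edge 4 -> strength 9
  modes <- c("a", "b", "d", "a", "b", "d", "c", "b", "d", "c", "b", "d", "c", "b")
  net <- build_mode_network(modes)
  e <- net$edges
  in_b <- sum(e$weight[e$to == "b"])
  out_b <- sum(e$weight[e$from == "b"])
  expect_equal(node_strength(net, "b"), in_b + out_b)

  # handshake identity incl. self-loops, on random sequences
  withr::with_seed(43, {
    for (i in 1:20) {
      net <- build_mode_network(random_mode_seq(sample(8:40, 1)))
      expect_equal(sum(node_strength(net)$strength), 2 * sum(net$edges$weight))
    }
  })
  expect_error(node_strength(net, "zzz"), "not a node")
})

test_that("transmission probabilities equal the Markov MLE of the sequence", {
  withr::with_seed(47, {
    for (i in 1:100) {
      modes <- random_mode_seq(sample(10:50, 1))
      net <- build_mode_network(modes)
      probs <- transmission_probabilities(net)
      # per-node normalization
      by_from <- tapply(probs$probability, probs$from, sum)
      expect_equal(as.vector(by_from), rep(1, length(by_from)))
      # count-based conditional frequencies from the raw sequence
      from <- modes[-length(modes)]
      to <- modes[-1]
      for (r in sample(nrow(probs), min(5, nrow(probs)))) {
        cond <- sum(from == probs$from[r] & to == probs$to[r]) /
          sum(from == probs$from[r])
        expect_equal(probs$probability[r], cond)
      }
    }
  })
})

test_that("sink nodes yield an empty transition table with a warning", {
  net <- build_mode_network(c("A", "B", "C")) # C is a sink
  expect_warning(out <- transmission_probabilities(net, "C"), "sink")
  expect_equal(nrow(out), 0)
})

test_that("key modes are ranked by strength with lexicographic tie-breaks", {
  modes <- c("h", "a", "h", "b", "h", "c", "h", "d")
  net <- build_mode_network(modes)
  km <- key_modes(net)
  expect_equal(km$mode[1], "h") # the hub dominates
  expect_equal(km$cumulative_share[nrow(km)], 1)
  # determinism across identical builds
  expect_identical(km, key_modes(build_mode_network(modes)))
  # lexicographic ties: all non-hub modes have equal strength
  tied <- km$mode[km$strength == 2]
  expect_equal(tied, sort(tied))
})

test_that("top modes on a heavy-tailed network out-carry a degree-shuffled null", {
  pair <- simulate_pair(synth_config(n_weeks = 176, seed = 19,
                                     coupling_strength = 1.2, dispersion = Inf))
  scen <- build_scenarios(pair, l_max = 16)
  cors <- suppressMessages(symbolize(correlation_sequences(scen, window = 3)))
  modes <- mode_sequences(cors, omega = 3)
  net <- build_mode_network(modes$mode[modes$L == -10])
  km <- key_modes(net, top_k = 7)
  top7_share <- km$cumulative_share[7]
  # null: strengths spread evenly over the N nodes
  expect_gt(top7_share, 7 / net$N)
  # and beats random reassignments of the observed strengths to ranks
  strengths <- node_strength(net)$strength
  withr::with_seed(11, {
    null_shares <- replicate(200, {
      sum(sample(strengths, 7)) / sum(strengths)
    })
  })
  expect_gt(top7_share, stats::quantile(null_shares, 0.95))
})

test_that("log-log OLS matches a normal-equations oracle", {
  withr::with_seed(53, {
    for (i in 1:20) {
      degrees <- sample(1:30, 200, replace = TRUE, prob = (1:30)^-1.8)
      fit <- fit_power_law(degrees)
      tab <- table(degrees)
      lx <- log10(as.numeric(names(tab)))
      ly <- log10(as.numeric(tab) / length(degrees))
      n <- length(lx)
      slope <- (n * sum(lx * ly) - sum(lx) * sum(ly)) /
        (n * sum(lx^2) - sum(lx)^2)
      intercept <- mean(ly) - slope * mean(lx)
      expect_equal(fit$b, -slope, tolerance = 1e-10)
      expect_equal(fit$a, 10^intercept, tolerance = 1e-10)
      expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
    }
  })
})

test_that("the fitted exponent recovers an analytic power law", {
  # counts set proportionally to P(k) = c * k^-2 over k = 1..20
  k <- 1:20
  counts <- round(1e5 * k^-2)
  degrees <- rep(k, counts)
  fit <- fit_power_law(degrees)
  expect_lt(abs(fit$b - 2), 0.05)
  expect_gt(fit$r_squared, 0.99)
})

test_that("degenerate degree distributions are rejected", {
  expect_error(fit_power_law(rep(4, 50)), "3 distinct")
  expect_error(fit_power_law(c(-1, 2, 3)), "nonnegative")
})

test_that("network export writes GraphML and an edge-list CSV", {
  net <- build_mode_network(c("AAB", "ABB", "AAB", "AAB", "ABB"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mode_network(net, gml, csv)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), net$N)
  expect_equal(igraph::ecount(reread), net$E)
  edges <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(names(edges), c("source", "target", "weight"))
  expect_equal(sum(edges$weight), 4)
})
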