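test_that("window correlation matches term-by-term summation on random windows", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  withr::with_seed(17, {
    for (i in 1:120) {
      x <- rnorm(5)
      y <- rnorm(5)
      expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
    }
  })
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1, 1), "at least 2")
})

test_that("window correlation is affine-invariant and flags constant windows", {
  withr::with_seed(31, {
    for (i in 1:40) {
      x <- rnorm(6)
      y <- rnorm(6)
      r <- pearson_r(x, y)
      expect_equal(pearson_r(2.5 * x + 7, y), r, tolerance = 1e-12)
      expect_equal(pearson_r(x, 0.3 * y - 2), r, tolerance = 1e-12)
      expect_equal(pearson_r(-x, y), -r, tolerance = 1e-12)
    }
  })
  expect_true(is.na(pearson_r(rep(1, 4), 1:4)))
})

test_that("symbolization maps the printed brackets and partitions [-1, 1]", {
  expect_equal(symbolize(0.85), "A")
  expect_equal(symbolize(0.8), "A")
  expect_equal(symbolize(0.3), "B")
  expect_equal(symbolize(0), "C")
  expect_equal(symbolize(-0.3), "D")
  expect_equal(symbolize(-0.8), "E")
  expect_equal(symbolize(c(1, -1)), c("A", "E"))
  expect_equal(symbolize(NA_real_), "C") # undefined -> no correlation
  expect_error(symbolize(1.01), "\\[-1, 1\\]")

  # total function: a fine grid lands in exactly one of the five levels
  grid <- seq(-1, 1, by = 1e-4)
  syms <- symbolize(grid)
  expect_true(all(syms %in% c("A", "B", "C", "D", "E")))
  # and the level boundaries sit exactly where the brackets say
  expect_equal(as.vector(table(syms)[c("A", "E")]),
               c(sum(grid >= 0.8), sum(grid <= -0.8)))
})

test_that("correlation sequences have length (n - |L|) - T + 1 per scenario", {
  pair <- simulate_pair(synth_config(n_weeks = 176, seed = 8))
  scen <- build_scenarios(pair, l_max = 16)
  for (t_win in c(3, 5)) {
    cors <- suppressMessages(correlation_sequences(scen, window = t_win))
    lens <- dplyr::count(cors, L)
    expect_equal(lens$n, 177 - abs(-16:16) - t_win)
  }
  expect_error(correlation_sequences(scen, window = 1), "window")
})

test_that("a lag-shifted affine copy gives r = +1 across its own scenario", {
  n <- 60
  l <- 4 # index series lags the counts by 4 weeks
  x <- withr::with_seed(23, cumsum(rnorm(n, 0, 1)) + 50)
  y <- numeric(n)
  y[1:(n - l)] <- 2 * x[(1 + l):n] + 3
  pair <- tibble::tibble(
    date = as.Date("2020-01-06") + 7 * (0:(n - 1)),
    index_value = x, deaths = y
  )
  cors <- suppressMessages(correlation_sequences(build_scenarios(pair, l_max = 6), 3))
  target <- cors[cors$L == l & cors$window_start <= n - l - 3, ]
  expect_true(all(abs(target$r - 1) < 1e-9))
})

test_that("zero-variance windows symbolize to C without breaking lengths", {
  pair <- tibble::tibble(
    date = as.Date("2020-01-06") + 7 * (0:19),
    index_value = rnorm(20) + 100,
    deaths = rep(5L, 20) # constant counts: every window undefined
  )
  cors <- suppressMessages(correlation_sequences(build_scenarios(pair, l_max = 2), 3))
  expect_true(all(cors$undefined))
  expect_equal(nrow(cors), sum(21 - abs(-2:2) - 3))
  expect_true(all(symbolize(cors)$symbol == "C"))
})

test_that("coarse-graining slides a step-1 window over the symbols", {
  expect_equal(
    coarse_grain(c("C", "D", "B", "D", "B"), omega = 3),
    c("CDB", "DBD", "BDB")
  )
  syms <- c("A", "B", "C", "D")
  expect_equal(coarse_grain(syms, omega = 1), syms)
  expect_error(coarse_grain(syms, omega = 5), "exceeds")
  # consecutive modes share omega - 1 letters by construction
  withr::with_seed(5, {
    s <- sample(c("A", "B", "C", "D", "E"), 30, replace = TRUE)
    m <- coarse_grain(s, 3)
    for (i in seq_len(length(m) - 1)) {
      expect_equal(substr(m[i], 2, 3), substr(m[i + 1], 1, 2))
    }
  })
})

test_that("mode sequences have length (n - |L|) - T - omega + 2 per scenario", {
  pair <- simulate_pair(synth_config(n_weeks = 176, seed = 8))
  scen <- build_scenarios(pair, l_max = 16)
  cors <- suppressMessages(symbolize(correlation_sequences(scen, window = 3)))
  modes <- mode_sequences(cors, omega = 3)
  lens <- dplyr::count(modes, L)
  expect_equal(lens$n, 178 - abs(-16:16) - 3 - 3)
  expect_true(all(nchar(modes$mode) == 3))
  expect_lte(dplyr::n_distinct(modes$mode), 125)
})

test_that("symbol profiles are proper per-scenario distributions", {
  pair <- simulate_pair(synth_config(n_weeks = 140, seed = 10))
  scen <- build_scenarios(pair, l_max = 16)
  cors <- suppressMessages(symbolize(correlation_sequences(scen, window = 3)))
  prof <- symbol_profile(cors)
  expect_equal(nrow(prof), 33)
  sums <- rowSums(prof[, c("A", "B", "C", "D", "E")])
  expect_equal(unname(sums), rep(1, 33))

  # degenerate sequences
  toy <- tibble::tibble(L = 0L, window = 3L, symbol = c("A", "B", "A", "B"))
  p <- symbol_profile(toy)
  expect_equal(p$A, 0.5)
  expect_equal(p$B, 0.5)
  expect_equal(p$C, 0)
})

test_that("scenario selection keeps the lags least dominated by no-correlation", {
  pair <- simulate_pair(synth_config(n_weeks = 176, seed = 12))
  scen <- build_scenarios(pair, l_max = 16)
  prof <- symbol_profile(
    suppressMessages(symbolize(correlation_sequences(scen, window = 3)))
  )
  sel <- select_scenarios(prof, n_select = 9)
  expect_equal(nrow(sel), 9)
  expect_lte(max(sel$C), min(prof$C[!prof$L %in% sel$L]))
})
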