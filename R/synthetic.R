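#' Configuration for the synthetic weekly series generator
#'
#' Bundles every parameter of the synthetic index/count generator into a
#' validated list. The generator emulates the kind of data the pipeline is
#' designed for: a smooth, autocorrelated weekly economic index with episodic
#' drift regimes, and an overdispersed nonnegative weekly count series whose
#' intensity is coupled to earlier index movements at a known lag. Because the
#' coupling lag, sign, strength and periodicity are chosen here, downstream
#' lag-scan and spectral results can be checked against a known truth.
#'
#' @param n_weeks Number of weekly points to generate. Must be at least
#'   `2 * 16 + coupling_lag + 10` so that every lag scenario in a default
#'   scan retains a usable paired series.
#' @param seed Integer seed. Each internal operation draws from its own
#'   sub-stream derived from this seed, so output is bitwise reproducible.
#' @param index_start Initial index level (must be positive).
#' @param index_drift_segments Data frame or tibble with columns `length`
#'   (weeks) and `drift` (percent per week); segment lengths must sum to
#'   `n_weeks`. Successive segments give the index its episodic rise/decline
#'   regimes.
#' @param index_noise_sd Standard deviation of the weekly multiplicative
#'   noise, in percent per week (nonnegative).
#' @param coupling_lag Lag in weeks between an index movement and the count
#'   response; positive means counts respond to index changes that happened
#'   `coupling_lag` weeks earlier.
#' @param coupling_sign Either `+1` or `-1`: sign of the count response to an
#'   index increase.
#' @param coupling_strength Nonnegative coupling strength, in log-intensity
#'   units per percent of weekly index change. `0` decouples the series.
#' @param base_intensity Mean weekly count when uncoupled (positive).
#' @param dispersion Negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @param period_weeks Optional period (weeks) of a sinusoidal modulation of
#'   the coupling; `NULL` for no modulation.
#' @param start_date Date of the first week (used when writing CSV output).
#'
#' @return A list of class `synth_config`.
#' @seealso [simulate_pair()]
#' @export
#' @examples
#' cfg <- synth_config(n_weeks = 120, seed = 1, coupling_lag = 8)
#' cfg$coupling_lag
synth_config <- function(n_weeks = 176L,
                         seed = 1L,
                         index_start = 100,
                         index_drift_segments = NULL,
                         index_noise_sd = 0.8,
                         coupling_lag = 10L,
                         coupling_sign = -1L,
                         coupling_strength = 0.6,
                         base_intensity = 12,
                         dispersion = 8,
                         period_weeks = NULL,
                         start_date = as.Date("2012-07-01")) {
  check_scalar_int(n_weeks, "n_weeks", min = 2)
  check_scalar_int(seed, "seed")
  check_scalar_int(coupling_lag, "coupling_lag")
  if (coupling_lag >= n_weeks) {
    abort("`coupling_lag` must be smaller than `n_weeks`.")
  }
  if (!coupling_sign %in% c(-1, 1)) {
    abort("`coupling_sign` must be +1 or -1.")
  }
  if (!is.numeric(index_start) || index_start <= 0) {
    abort("`index_start` must be a positive number.")
  }
  if (!is.numeric(index_noise_sd) || index_noise_sd < 0) {
    abort("`index_noise_sd` must be nonnegative.")
  }
  if (!is.numeric(coupling_strength) || coupling_strength < 0) {
    abort("`coupling_strength` must be nonnegative.")
  }
  if (!is.numeric(base_intensity) || base_intensity <= 0) {
    abort("`base_intensity` must be positive.")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    abort("`dispersion` must be positive (use Inf for Poisson counts).")
  }
  if (!is.null(period_weeks) && (!is.numeric(period_weeks) || period_weeks <= 0)) {
    abort("`period_weeks` must be NULL or a positive number.")
  }
  if (is.null(index_drift_segments)) {
    index_drift_segments <- default_drift_segments(n_weeks)
  }
  index_drift_segments <- as_tibble(index_drift_segments)
  if (!all(c("length", "drift") %in% names(index_drift_segments))) {
    abort("`index_drift_segments` needs columns `length` and `drift`.")
  }
  if (any(index_drift_segments$length <= 0) ||
      any(index_drift_segments$length != round(index_drift_segments$length))) {
    abort("`index_drift_segments`: segment lengths must be positive integers.")
  }
  if (sum(index_drift_segments$length) != n_weeks) {
    abort(sprintf(
      "`index_drift_segments`: segment lengths sum to %d but `n_weeks` is %d.",
      sum(index_drift_segments$length), n_weeks
    ))
  }
  structure(
    list(
      n_weeks = as.integer(n_weeks),
      seed = as.integer(seed),
      index_start = index_start,
      index_drift_segments = index_drift_segments,
      index_noise_sd = index_noise_sd,
      coupling_lag = as.integer(coupling_lag),
      coupling_sign = as.integer(coupling_sign),
      coupling_strength = coupling_strength,
      base_intensity = base_intensity,
      dispersion = dispersion,
      period_weeks = period_weeks,
      start_date = as.Date(start_date)
    ),
    class = "synth_config"
  )
}

# Default drift regimes: a moderate rise, a long decline, a flat stretch and a
# mild decline, scaled to fill n_weeks. Weekly drifts sit in the few-tenths of
# a percent range typical of a slow-moving commodity price index.
default_drift_segments <- function(n_weeks) {
  base <- c(0.17, 0.34, 0.23, 0.26)
  lens <- floor(base * n_weeks)
  lens[4] <- n_weeks - sum(lens[1:3])
  tibble(length = as.integer(lens), drift = c(0.3, -0.6, 0.0, -0.4))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  n_weeks: %d   seed: %d\n", x$n_weeks, x$seed))
  cat(sprintf(
    "  index: start %.4g, noise sd %.4g %%/wk, %d drift segment(s)\n",
    x$index_start, x$index_noise_sd, nrow(x$index_drift_segments)
  ))
  cat(sprintf(
    "  coupling: lag %d wk, sign %+d, strength %.4g\n",
    x$coupling_lag, x$coupling_sign, x$coupling_strength
  ))
  cat(sprintf(
    "  counts: base intensity %.4g/wk, dispersion %s, period %s\n",
    x$base_intensity, format(x$dispersion),
    if (is.null(x$period_weeks)) "none" else paste0(x$period_weeks, " wk")
  ))
  invisible(x)
}

#' Generate the synthetic weekly index series
#'
#' Multiplicative random walk `v[t+1] = v[t] * (1 + drift[t]/100 + eps[t])`
#' with `eps[t] ~ Normal(0, (index_noise_sd/100)^2)` and per-week drift taken
#' from the configured drift segments. All values stay strictly positive
#' (the step multiplier is floored just above zero); output is deterministic
#' given the seed.
#'
#' @param config A [synth_config()].
#' @return Numeric vector of length `n_weeks`.
#' @export
#' @examples
#' generate_index(synth_config(n_weeks = 60, seed = 3, index_noise_sd = 0))[1:5]
generate_index <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_weeks
  drift <- rep(config$index_drift_segments$drift,
               times = config$index_drift_segments$length)
  eps <- with_op_seed(config$seed, "generate_index", {
    rnorm(n - 1L, mean = 0, sd = config$index_noise_sd / 100)
  })
  v <- numeric(n)
  v[1] <- config$index_start
  for (t in seq_len(n - 1L)) {
    step <- 1 + drift[t] / 100 + eps[t]
    v[t + 1L] <- v[t] * max(step, 1e-6)
  }
  v
}

#' Generate the synthetic weekly count series
#'
#' Draws weekly counts whose log-intensity responds to earlier weekly
#' percentage changes of the index:
#' `lambda[t] = base_intensity * exp(sign * strength * dp[t - lag] * m[t])`
#' where `dp` is the week-over-week percent change of the index (taken as 0
#' where the lagged week falls before the series start), and
#' `m[t] = 1 + sin(2*pi*t/period_weeks)` when a coupling period is configured
#' (otherwise 1). Counts are negative binomial with the configured dispersion
#' (Poisson when `dispersion = Inf`); deterministic given the seed.
#'
#' @param index Numeric index series of length `n_weeks` (normally from
#'   [generate_index()]).
#' @inheritParams generate_index
#' @return Integer vector of counts with attribute `"intensity"` holding the
#'   per-week intensity `lambda`.
#' @export
generate_counts <- function(index, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_weeks
  if (length(index) != n) {
    abort("`index` must have length `n_weeks`.")
  }
  dp <- c(0, 100 * diff(index) / index[-n])
  lag <- config$coupling_lag
  idx <- seq_len(n) - lag
  dp_lagged <- ifelse(idx >= 1 & idx <= n, dp[pmax(pmin(idx, n), 1L)], 0)
  m <- if (is.null(config$period_weeks)) {
    rep(1, n)
  } else {
    1 + sin(2 * pi * seq_len(n) / config$period_weeks)
  }
  lambda <- config$base_intensity *
    exp(config$coupling_sign * config$coupling_strength * dp_lagged * m)
  counts <- with_op_seed(config$seed, "generate_counts", {
    if (is.infinite(config$dispersion)) {
      rpois(n, lambda)
    } else {
      rnbinom(n, size = config$dispersion, mu = lambda)
    }
  })
  structure(as.integer(counts), intensity = lambda)
}

#' Simulate a coupled index/count weekly series pair
#'
#' Runs [generate_index()] and [generate_counts()] and assembles the pair
#' into the tabular form the rest of the pipeline consumes, with the
#' ground-truth coupling parameters attached for recovery tests.
#'
#' @inheritParams generate_index
#' @return A tibble with columns `date` (consecutive weekly dates),
#'   `index_value` and `deaths`, of class `acfm_pair`, carrying a
#'   `"truth"` attribute (see [synthetic_truth()]).
#' @export
#' @examples
#' pair <- simulate_pair(synth_config(n_weeks = 80, seed = 42))
#' head(pair)
#' synthetic_truth(pair)[c("coupling_lag", "coupling_sign")]
simulate_pair <- function(config = synth_config()) {
  index <- generate_index(config)
  counts <- generate_counts(index, config)
  pair <- tibble(
    date = config$start_date + 7L * (seq_len(config$n_weeks) - 1L),
    index_value = index,
    deaths = as.integer(counts)
  )
  truth <- structure(
    list(
      coupling_lag = config$coupling_lag,
      coupling_sign = config$coupling_sign,
      coupling_strength = config$coupling_strength,
      period_weeks = config$period_weeks,
      index = index,
      counts = as.integer(counts),
      intensity = attr(counts, "intensity")
    ),
    class = "synthetic_truth"
  )
  class(pair) <- c("acfm_pair", class(pair))
  attr(pair, "truth") <- truth
  pair
}

#' Ground truth attached to a simulated pair
#'
#' @param pair A pair produced by [simulate_pair()].
#' @return A list of class `synthetic_truth` with the coupling parameters and
#'   realized series, or `NULL` for pairs loaded from files.
#' @export
synthetic_truth <- function(pair) {
  attr(pair, "truth")
}

#' Write a series pair to CSV (with optional truth sidecar)
#'
#' @param pair Tibble with columns `date`, `index_value`, `deaths`.
#' @param path Output CSV path.
#' @param truth_path Optional path for a JSON sidecar with the ground-truth
#'   coupling parameters (only written when the pair carries a truth).
#' @return `path`, invisibly.
#' @export
write_pair <- function(pair, path, truth_path = NULL) {
  readr::write_csv(pair[c("date", "index_value", "deaths")], path)
  truth <- synthetic_truth(pair)
  if (!is.null(truth_path) && !is.null(truth)) {
    jsonlite::write_json(
      list(
        coupling_lag = truth$coupling_lag,
        coupling_sign = truth$coupling_sign,
        coupling_strength = truth$coupling_strength,
        period_weeks = truth$period_weeks
      ),
      truth_path,
      auto_unbox = TRUE, null = "null", digits = NA
    )
  }
  invisible(path)
}
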