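#' Pearson product-moment correlation of one paired window
#'
#' Two-pass mean-centered computation of the sample correlation coefficient
#' for a single sliding window. Windows in which either series has zero
#' variance (for example a run of identical weekly counts) have no defined
#' correlation; these return `NA` so callers can flag them rather than drop
#' the window and break the sequence-length bookkeeping.
#'
#' @param x,y Numeric vectors of equal length `>= 2`.
#' @return The correlation in `[-1, 1]`, or `NA` when either window is
#'   constant.
#' @export
#' @examples
#' pearson_r(1:3, c(3, 2, 1))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.")
  }
  if (length(x) < 2L) {
    abort("windows must contain at least 2 points.")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) {
    return(NA_real_)
  }
  r <- sum(xc * yc) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Sliding-window lagged correlation sequences
#'
#' For each lag scenario, slides a window of `window` weeks along the paired
#' series with step 1 and records the Pearson correlation of every window.
#' For a series of length `n`, scenario `L` yields `(n - |L|) - window + 1`
#' coefficients (with `n = 176` and window `T`: `177 - |L| - T`).
#'
#' @param scenarios Scenario table from [build_scenarios()].
#' @param window Window length `T` in weeks (the reference analysis uses 3,
#'   4 and 5; default 3).
#' @return A tibble with columns `L`, `window`, `window_start` (1-based
#'   position of the window in the paired series), `r`, and `undefined`
#'   (`TRUE` where a zero-variance window made `r` undefined).
#' @export
correlation_sequences <- function(scenarios, window = 3L) {
  check_scalar_int(window, "window", min = 2)
  out <- purrr::pmap_dfr(
    scenarios[c("L", "x", "y")],
    function(L, x, y) {
      n_pairs <- length(x)
      if (window > n_pairs) {
        abort(sprintf(
          "window %d exceeds the %d paired points of scenario L = %d.",
          window, n_pairs, L
        ))
      }
      starts <- seq_len(n_pairs - window + 1L)
      r <- vapply(starts, function(w) {
        idx <- w:(w + window - 1L)
        pearson_r(x[idx], y[idx])
      }, numeric(1))
      tibble(
        L = L, window = as.integer(window),
        window_start = starts, r = r, undefined = is.na(r)
      )
    }
  )
  n_undef <- sum(out$undefined)
  if (n_undef > 0) {
    inform(sprintf(
      "%d of %d windows had zero variance; their correlation is undefined and will symbolize to 'C'.",
      n_undef, nrow(out)
    ))
  }
  out
}

#' Whole-series correlation per scenario
#'
#' The single correlation coefficient of each scenario's full paired series —
#' the "overall" curve that summarizes how correlation varies across lags,
#' complementing the sliding-window sequences.
#'
#' @inheritParams correlation_sequences
#' @return A tibble with columns `L`, `n_pairs`, `r`.
#' @export
overall_correlations <- function(scenarios) {
  purrr::pmap_dfr(
    scenarios[c("L", "x", "y")],
    function(L, x, y) tibble(L = L, n_pairs = length(x), r = pearson_r(x, y))
  )
}

#' Symbolize correlation coefficients into five levels
#'
#' Discretizes each coefficient into the five correlation levels
#' \describe{
#'   \item{A}{strong positive, `r` in `[0.8, 1.0]`}
#'   \item{B}{weak positive, `r` in `[0.3, 0.8)`}
#'   \item{C}{no correlation, `r` in `(-0.3, 0.3)`}
#'   \item{D}{weak negative, `r` in `(-0.8, -0.3]`}
#'   \item{E}{strong negative, `r` in `[-1.0, -0.8]`}
#' }
#' The five intervals partition `[-1, 1]` exactly. Undefined coefficients
#' (`NA`, from zero-variance windows) map to `C`, the no-correlation level.
#'
#' @param r Numeric vector of coefficients in `[-1, 1]` (NA allowed), or a
#'   correlation tibble from [correlation_sequences()], in which case a
#'   `symbol` column is appended.
#' @param cutoffs Length-2 numeric `c(weak, strong)` giving the inner and
#'   outer cut points (default `c(0.3, 0.8)`).
#' @return A character vector of symbols, or the input tibble with a
#'   `symbol` column.
#' @export
#' @examples
#' symbolize(c(0.85, 0.3, 0, -0.3, -0.8))
symbolize <- function(r, cutoffs = c(0.3, 0.8)) {
  if (is.data.frame(r)) {
    r$symbol <- symbolize(r$r, cutoffs = cutoffs)
    return(r)
  }
  if (any(r < -1 | r > 1, na.rm = TRUE)) {
    abort("correlation coefficients must lie in [-1, 1].")
  }
  if (length(cutoffs) != 2L || cutoffs[1] <= 0 || cutoffs[2] <= cutoffs[1] ||
      cutoffs[2] >= 1) {
    abort("`cutoffs` must satisfy 0 < weak < strong < 1.")
  }
  weak <- cutoffs[1]
  strong <- cutoffs[2]
  out <- rep("C", length(r))
  out[r >= strong] <- "A"
  out[r >= weak & r < strong] <- "B"
  out[r <= -weak & r > -strong] <- "D"
  out[r <= -strong] <- "E"
  out[is.na(r)] <- "C"
  out
}

#' Coarse-grain a symbol sequence into fluctuation modes
#'
#' Slides a second window of `omega` symbols (step 1) along a symbol
#' sequence, concatenating each window into one fluctuation mode — an
#' `omega`-letter word over \{A..E\} describing a short pattern of
#' correlation change. A sequence of `m` symbols yields `m - omega + 1`
#' modes; with `n = 176`, lag `L` and window `T` this is
#' `178 - |L| - T - omega`. At most `5^omega` distinct modes exist (125 for
#' the default `omega = 3`).
#'
#' @param symbols Character vector of single-letter symbols.
#' @param omega Mode length (positive integer, default 3).
#' @return Character vector of modes.
#' @export
#' @examples
#' coarse_grain(c("C", "D", "B", "D", "B"), omega = 3)
coarse_grain <- function(symbols, omega = 3L) {
  check_scalar_int(omega, "omega", min = 1)
  m <- length(symbols)
  if (omega > m) {
    abort(sprintf("`omega` (%d) exceeds the symbol-sequence length (%d).", omega, m))
  }
  starts <- seq_len(m - omega + 1L)
  vapply(starts, function(i) {
    paste(symbols[i:(i + omega - 1L)], collapse = "")
  }, character(1))
}

#' Fluctuation-mode sequences for every scenario
#'
#' Applies [coarse_grain()] per lag scenario to a symbolized correlation
#' table.
#'
#' @param symbols_tbl Output of [symbolize()] applied to
#'   [correlation_sequences()] (columns `L`, `window`, `symbol`).
#' @param omega Mode length (default 3).
#' @return A tibble with columns `L`, `window`, `omega`, `position`, `mode`.
#' @export
mode_sequences <- function(symbols_tbl, omega = 3L) {
  symbols_tbl |>
    dplyr::arrange(.data$L, .data$window, .data$window_start) |>
    dplyr::reframe(
      omega = as.integer(omega),
      position = seq_len(length(.data$symbol) - omega + 1L),
      mode = coarse_grain(.data$symbol, omega),
      .by = c("L", "window")
    )
}

#' Per-scenario symbol frequency profile
#'
#' Tabulates, for every lag scenario, the proportion of each of the five
#' correlation levels in its symbol sequence. The scenario that maximizes the
#' strong-level proportions points at the lag where the two series are most
#' tightly coupled.
#'
#' @inheritParams mode_sequences
#' @return A tibble with columns `L`, `window`, one proportion column per
#'   symbol (`A` ... `E`), and `n_symbols`. Proportions sum to 1 per row.
#' @export
symbol_profile <- function(symbols_tbl) {
  counts <- symbols_tbl |>
    dplyr::count(.data$L, .data$window, .data$symbol) |>
    tidyr::complete(
      tidyr::nesting(L, window),
      symbol = symbol_alphabet(),
      fill = list(n = 0L)
    )
  counts |>
    dplyr::group_by(.data$L, .data$window) |>
    dplyr::mutate(prop = .data$n / sum(.data$n), n_symbols = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "symbol", values_from = "prop") |>
    dplyr::relocate("n_symbols", .after = dplyr::last_col())
}

#' Rank scenarios for network construction
#'
#' Orders lag scenarios by ascending proportion of the no-correlation symbol
#' `C` (ties broken by smaller `|L|`, then `L`) and keeps the first
#' `n_select`. This favors the scenarios whose correlation structure is most
#' informative — those least dominated by uncorrelated windows.
#'
#' @param profile Output of [symbol_profile()].
#' @param n_select Number of scenarios to keep (default 9).
#' @return The selected rows of `profile`, ranked, with a `rank` column.
#' @export
select_scenarios <- function(profile, n_select = 9L) {
  check_scalar_int(n_select, "n_select", min = 1)
  profile |>
    dplyr::arrange(.data$C, abs(.data$L), .data$L) |>
    dplyr::slice_head(n = n_select) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
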