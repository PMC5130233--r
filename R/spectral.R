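#' Periodogram of a correlation-coefficient (or any real) sequence
#'
#' Discrete-Fourier periodogram at the Fourier frequencies `k/n`,
#' `k = 1..floor(n/2)`, after removing a linear trend from the series (which
#' also removes the mean). Power is normalized as `|X_k|^2 / n`, with the
#' Nyquist term (even `n`) halved so that the total power equals exactly half
#' the detrended sum of squares — i.e. `sum(power) = n/2 * var` with
#' `var = sum((x - xbar)^2) / n` of the detrended series (a Parseval
#' identity). The dominant period is the reciprocal of the highest-power
#' frequency, so its resolution is limited to `n/k` weeks.
#'
#' @param series Numeric vector, length `>= 8`.
#' @param detrend Remove a linear trend first (default `TRUE`).
#' @param taper Apply a Hann window after detrending (default `FALSE`; the
#'   bare periodogram is the primary analysis).
#' @return An object of class `acfm_periodogram`: list with `frequency`
#'   (cycles/week), `period` (weeks), `power`, `dominant_period`,
#'   `dominant_power_fraction`, `n`, and `flat` (`TRUE` for a constant
#'   series, whose spectrum carries no information).
#' @export
#' @examples
#' p <- periodogram(sin(2 * pi * (1:52) / 13))
#' p$dominant_period
periodogram <- function(series, detrend = TRUE, taper = FALSE) {
  n <- length(series)
  if (n < 8L) {
    abort("`series` must have length >= 8.")
  }
  if (anyNA(series)) {
    abort("`series` must not contain missing values.")
  }
  x <- if (detrend) {
    stats::residuals(lm(series ~ seq_len(n)))
  } else {
    series - mean(series)
  }
  flat <- isTRUE(all.equal(var(x), 0)) || all(x == 0)
  if (taper) {
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  k <- seq_len(n %/% 2)
  xf <- fft(x)[k + 1L]
  power <- Mod(xf)^2 / n
  if (n %% 2L == 0L) {
    power[length(power)] <- power[length(power)] / 2
  }
  freq <- k / n
  dom <- which.max(power)
  structure(
    list(
      frequency = freq,
      period = 1 / freq,
      power = power,
      dominant_period = if (flat) NA_real_ else 1 / freq[dom],
      dominant_power_fraction = if (flat) NA_real_ else power[dom] / sum(power),
      n = n,
      flat = flat
    ),
    class = "acfm_periodogram"
  )
}

#' @export
print.acfm_periodogram <- function(x, ...) {
  if (x$flat) {
    cat("<acfm_periodogram> flat spectrum (constant series), n =", x$n, "\n")
  } else {
    cat(sprintf(
      "<acfm_periodogram> n = %d, dominant period = %.3g weeks (%.1f%% of power)\n",
      x$n, x$dominant_period, 100 * x$dominant_power_fraction
    ))
  }
  invisible(x)
}

#' Periodicity of a correlation sequence from random fixed-length segments
#'
#' Draws `n_segments` segment start positions uniformly without replacement
#' (seeded, hence reproducible), computes the periodogram of each
#' `segment_length`-week segment of the correlation-coefficient sequence, and
#' summarizes the dominant periods. A consistent modal dominant period across
#' segments indicates genuine periodicity in the correlation dynamics rather
#' than a windowing artifact.
#'
#' @param r Numeric vector of correlation coefficients (one scenario's `r`
#'   sequence; `NA` values from undefined windows are replaced by 0, the
#'   no-correlation value). A correlation tibble filtered to one lag also
#'   works.
#' @param segment_length Segment length in weeks (default 50).
#' @param n_segments Number of segments (default 4). Capped at the number of
#'   distinct start positions.
#' @param seed Integer seed for the segment draw.
#' @return A list of class `segment_periodicity`: `segments` (tibble
#'   `segment_start`, `dominant_period`, `dominant_power_fraction`),
#'   `modal_period` (most frequent dominant period; smallest on ties),
#'   `periodograms` (list), `segment_length`.
#' @export
segment_periodicity <- function(r, segment_length = 50L, n_segments = 4L,
                                seed = 1L) {
  if (is.data.frame(r)) {
    r <- r$r
  }
  check_scalar_int(segment_length, "segment_length", min = 8)
  check_scalar_int(n_segments, "n_segments", min = 1)
  r[is.na(r)] <- 0
  m <- length(r)
  if (m < segment_length) {
    abort(sprintf(
      "sequence length %d is shorter than the %d-week segment.",
      m, segment_length
    ))
  }
  n_starts <- m - segment_length + 1L
  n_segments <- min(n_segments, n_starts)
  starts <- with_op_seed(seed, "segment_periodicity", {
    sort(sample.int(n_starts, n_segments, replace = FALSE))
  })
  pgs <- purrr::map(starts, function(s) {
    periodogram(r[s:(s + segment_length - 1L)])
  })
  seg_tbl <- tibble(
    segment_start = starts,
    dominant_period = purrr::map_dbl(pgs, "dominant_period"),
    dominant_power_fraction = purrr::map_dbl(pgs, "dominant_power_fraction")
  )
  dp <- seg_tbl$dominant_period[!is.na(seg_tbl$dominant_period)]
  modal <- if (length(dp) == 0L) {
    NA_real_
  } else {
    tab <- table(dp)
    as.numeric(min(as.numeric(names(tab)[tab == max(tab)])))
  }
  structure(
    list(
      segments = seg_tbl,
      modal_period = modal,
      periodograms = pgs,
      segment_length = as.integer(segment_length)
    ),
    class = "segment_periodicity"
  )
}

#' @export
print.segment_periodicity <- function(x, ...) {
  cat(sprintf(
    "<segment_periodicity> %d segment(s) of %d weeks; modal dominant period = %.3g weeks\n",
    nrow(x$segments), x$segment_length, x$modal_period
  ))
  print(x$segments)
  invisible(x)
}
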