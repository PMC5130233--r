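#' Aggregate dated event records into weekly bins
#'
#' Bins event-level records (one row per event, with a date and a count such
#' as deaths) into consecutive 7-day windows anchored at `start_date`. Bins
#' are half-open `[bin_start, bin_start + 7d)`; the bin grid runs from
#' `start_date` up to and including the last bin start that is `<= end_date`,
#' so a range whose end falls exactly on a bin start contributes a final
#' (possibly partial) bin of its own. The range 2012-07-01 to 2015-11-08, for
#' example, spans 175 full weeks and yields 176 bins.
#'
#' @param events Data frame with columns `date` (Date or ISO-8601 string) and
#'   `deaths` (nonnegative numbers). Zero-count events are allowed and
#'   events sharing a date are summed. An empty frame yields all-zero bins.
#' @param start_date,end_date Range covered by the bin grid (inclusive).
#' @return A tibble with columns `date` (bin start) and `deaths`
#'   (integer sum of event counts in the bin).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   date = as.Date("2020-01-06") + c(0, 6, 7),
#'   deaths = c(1, 2, 4)
#' )
#' aggregate_weekly(ev, as.Date("2020-01-06"), as.Date("2020-01-19"))
aggregate_weekly <- function(events, start_date, end_date) {
  start_date <- parse_iso_date(start_date, "start_date")
  end_date <- parse_iso_date(end_date, "end_date")
  if (end_date < start_date) {
    abort("`end_date` must not precede `start_date`.")
  }
  if (is.null(events) || nrow(events) == 0L) {
    events <- tibble(date = as.Date(character()), deaths = integer())
  }
  if (!all(c("date", "deaths") %in% names(events))) {
    abort("`events` needs columns `date` and `deaths`.")
  }
  dates <- parse_iso_date(events$date, "events$date")
  if (any(events$deaths < 0, na.rm = TRUE) || anyNA(events$deaths)) {
    bad <- which(is.na(events$deaths) | events$deaths < 0)
    abort(sprintf(
      "`events`: negative or missing deaths at row(s) %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  out_of_range <- dates < start_date | dates > end_date
  if (any(out_of_range)) {
    bad <- which(out_of_range)
    abort(sprintf(
      "`events`: %d record(s) outside [%s, %s]; first offenders at row(s) %s.",
      sum(out_of_range), start_date, end_date,
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  n_bins <- as.integer(floor(as.numeric(end_date - start_date) / 7)) + 1L
  bin_starts <- start_date + 7L * (seq_len(n_bins) - 1L)
  bin_of <- as.integer(floor(as.numeric(dates - start_date) / 7)) + 1L
  totals <- integer(n_bins)
  if (length(bin_of) > 0L) {
    sums <- tapply(as.numeric(events$deaths), bin_of, sum)
    totals[as.integer(names(sums))] <- as.integer(sums)
  }
  tibble(date = bin_starts, deaths = totals)
}

parse_iso_date <- function(x, name) {
  if (inherits(x, "Date")) {
    return(x)
  }
  parsed <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(parsed) & !anyNA(x)) {
    bad <- which(is.na(parsed))
    abort(sprintf(
      "`%s`: unparseable ISO-8601 date at row(s) %s.",
      name, paste(head(bad, 5), collapse = ", ")
    ))
  }
  parsed
}

#' Load and align an index/count series pair from CSV files
#'
#' Reads the continuous index series (columns `date`, `value` or
#' `index_value`) and the count series, validates alignment, and returns the
#' pipeline's standard pair table. The count file either already holds weekly
#' counts (columns `date`, `deaths`) or, with `events = TRUE`, holds dated
#' event records that are aggregated onto the index's weekly grid with
#' [aggregate_weekly()].
#'
#' @param index_csv Path to the index CSV.
#' @param deaths_csv Path to the weekly-counts or event-records CSV.
#' @param events If `TRUE`, treat `deaths_csv` as per-event records.
#' @return A tibble of class `acfm_pair` with columns `date`, `index_value`,
#'   `deaths`.
#' @export
load_pair <- function(index_csv, deaths_csv, events = FALSE) {
  index <- readr::read_csv(index_csv, show_col_types = FALSE)
  value_col <- intersect(c("index_value", "value"), names(index))[1]
  if (!"date" %in% names(index) || is.na(value_col)) {
    abort("`index_csv` needs columns `date` and `value` (or `index_value`).")
  }
  index <- tibble(
    date = parse_iso_date(index$date, "index date"),
    index_value = as.numeric(index[[value_col]])
  )
  if (anyNA(index$index_value)) {
    abort("`index_csv`: non-numeric or missing index values.")
  }
  deaths_raw <- readr::read_csv(deaths_csv, show_col_types = FALSE)
  if (!all(c("date", "deaths") %in% names(deaths_raw))) {
    abort("`deaths_csv` needs columns `date` and `deaths`.")
  }
  deaths <- if (events) {
    aggregate_weekly(deaths_raw, min(index$date), max(index$date) + 6L)
  } else {
    tibble(
      date = parse_iso_date(deaths_raw$date, "deaths date"),
      deaths = as.integer(deaths_raw$deaths)
    )
  }
  if (nrow(deaths) != nrow(index) || !all(deaths$date == index$date)) {
    abort(sprintf(
      "series are not aligned: index covers %s..%s (%d rows), deaths %s..%s (%d rows).",
      min(index$date), max(index$date), nrow(index),
      min(deaths$date), max(deaths$date), nrow(deaths)
    ))
  }
  pair <- validate_pair(tibble(
    date = index$date,
    index_value = index$index_value,
    deaths = deaths$deaths
  ))
  inform(sprintf(
    "loaded pair: n = %d weekly points, %s .. %s",
    nrow(pair), min(pair$date), max(pair$date)
  ))
  pair
}

validate_pair <- function(pair) {
  if (anyNA(pair$index_value) || anyNA(pair$deaths)) {
    abort("pair contains missing values; inputs must be complete.")
  }
  if (any(pair$deaths < 0)) {
    abort("`deaths` must be nonnegative.")
  }
  gaps <- diff(as.numeric(pair$date))
  if (length(gaps) && any(gaps != 7)) {
    abort("`date` must be strictly increasing with 7-day spacing.")
  }
  class(pair) <- unique(c("acfm_pair", class(pair)))
  pair
}

#' Construct the lag scenarios for the asynchronous-correlation scan
#'
#' Shifts the index series against the count series by every integer lag
#' `L` in `[-l_max, l_max]`, producing `2 * l_max + 1` scenarios (33 for the
#' default `l_max = 16`). Scenario `L` pairs `(x[t + L], y[t])` over all `t`
#' for which both indices exist, so positive `L` means the index observation
#' is `L` weeks later than the count observation (the index *lags* the
#' counts) and negative `L` means the index leads. Each scenario keeps
#' `n - |L|` pairs.
#'
#' @param pair A pair table with columns `index_value` and `deaths`
#'   (from [simulate_pair()] or [load_pair()]).
#' @param l_max Maximum lag in weeks (positive integer; default 16).
#' @return A tibble with one row per scenario: `L`, `n_pairs`, and
#'   list-columns `x` (index values) and `y` (counts).
#' @export
#' @examples
#' pair <- simulate_pair(synth_config(n_weeks = 80, seed = 1))
#' scen <- build_scenarios(pair, l_max = 4)
#' scen$n_pairs
build_scenarios <- function(pair, l_max = 16L) {
  check_scalar_int(l_max, "l_max", min = 1)
  x <- pair$index_value
  y <- pair$deaths
  n <- length(x)
  if (n <= l_max + 2L) {
    abort(sprintf("series length %d too short for l_max = %d.", n, l_max))
  }
  lags <- seq.int(-l_max, l_max)
  purrr::map_dfr(lags, function(L) {
    t_idx <- seq.int(max(1L, 1L - L), min(n, n - L))
    tibble(
      L = L,
      n_pairs = length(t_idx),
      x = list(x[t_idx + L]),
      y = list(y[t_idx])
    )
  })
}
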