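#' Configuration for a full pipeline run
#'
#' Collects every tunable of the end-to-end analysis. The defaults reproduce
#' the reference parameterization: a 16-week lag scan (33 scenarios),
#' correlation window `T = 3`, mode length `omega = 3`, symbol cutoffs 0.3
#' and 0.8, k-plex parameters `g = 3`, `sigma = 2`, 9 selected scenarios and
#' 50-week spectral segments.
#'
#' @param index_csv,deaths_csv Optional input CSV paths (see [load_pair()]);
#'   when `NULL`, data are simulated from `synthetic`.
#' @param events Treat `deaths_csv` as per-event records (default `FALSE`).
#' @param synthetic A [synth_config()] used when no files are given.
#' @param l_max,window,omega,cutoffs,g_size,sigma,n_select,segment_length,n_segments
#'   Stage parameters, as documented in the stage functions.
#' @param kplex_top_k Subgroups reported per network (default 6).
#' @param seed Seed for the spectral segment draw (and anything else random
#'   in the run).
#' @return A list of class `acfm_run_config`.
#' @export
pipeline_config <- function(index_csv = NULL, deaths_csv = NULL, events = FALSE,
                            synthetic = synth_config(),
                            l_max = 16L, window = 3L, omega = 3L,
                            cutoffs = c(0.3, 0.8),
                            g_size = 3L, sigma = 2L, kplex_top_k = 6L,
                            n_select = 9L, segment_length = 50L,
                            n_segments = 4L, seed = 1L) {
  structure(
    list(
      index_csv = index_csv, deaths_csv = deaths_csv, events = events,
      synthetic = synthetic,
      l_max = as.integer(l_max), window = as.integer(window),
      omega = as.integer(omega), cutoffs = cutoffs,
      g_size = as.integer(g_size), sigma = as.integer(sigma),
      kplex_top_k = as.integer(kplex_top_k),
      n_select = as.integer(n_select),
      segment_length = as.integer(segment_length),
      n_segments = as.integer(n_segments),
      seed = as.integer(seed)
    ),
    class = "acfm_run_config"
  )
}

#' Run the full asynchronous-correlation network pipeline
#'
#' Executes every stage in order — load or simulate the weekly pair, build
#' the lag scenarios, compute sliding-window correlation sequences, symbolize
#' and coarse-grain them into fluctuation modes, select the most informative
#' scenarios, build their mode-transition networks, and compute the network
#' statistics (key modes, power-law fit of the weighted-degree distribution,
#' k-plex subgroups, structural-hole profiles, path statistics) plus the
#' segment periodograms of the selected correlation sequences. Optionally
#' writes the full artifact bundle (tidy CSVs, GraphML networks, a JSON
#' report) to a directory.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for the artifact bundle; created if
#'   missing. `NULL` skips writing.
#' @return A list of class `acfm_run` with elements `pair`, `scenarios`,
#'   `correlations`, `overall`, `profile`, `modes`, `selected`, `networks`
#'   (tibble with list-columns `network`, `power_law`, `subgroups`,
#'   `structural_holes`, `paths`, `key_modes`, `spectral`), `report`
#'   (the JSON-ready summary list), and `config`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(synthetic = synth_config(n_weeks = 120, seed = 2)))
#' run$report$n_scenarios
#' }
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "acfm_run_config"))
  stage <- function(what, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)))
    })
  }
  pair <- stage("input", {
    if (!is.null(config$index_csv)) {
      load_pair(config$index_csv, config$deaths_csv, events = config$events)
    } else {
      simulate_pair(config$synthetic)
    }
  })
  inform(sprintf(
    "pipeline: n = %d weeks, l_max = %d, T = %d, omega = %d, seed = %d",
    nrow(pair), config$l_max, config$window, config$omega, config$seed
  ))
  scenarios <- stage("scenarios", build_scenarios(pair, l_max = config$l_max))
  correlations <- stage("correlation", {
    symbolize(correlation_sequences(scenarios, window = config$window),
              cutoffs = config$cutoffs)
  })
  overall <- stage("correlation", overall_correlations(scenarios))
  profile <- stage("symbolization", symbol_profile(correlations))
  modes <- stage("coarse-graining", mode_sequences(correlations, omega = config$omega))
  selected <- stage("selection", select_scenarios(profile, n_select = config$n_select))
  networks <- stage("networks", build_mode_networks(modes, lags = selected$L))
  networks <- stage("topology", {
    networks |>
      dplyr::mutate(
        power_law = purrr::map(.data$network, function(nw) {
          tryCatch(fit_power_law(nw), error = function(e) NULL)
        }),
        key_modes = purrr::map(.data$network, key_modes, top_k = 10L),
        subgroups = purrr::map(.data$network, enumerate_kplex,
                               g_size = config$g_size, sigma = config$sigma,
                               top_k = config$kplex_top_k),
        structural_holes = purrr::map(.data$network, structural_hole_profile),
        paths = purrr::map(.data$network, path_statistics)
      )
  })
  networks <- stage("spectral", {
    networks |>
      dplyr::mutate(
        spectral = purrr::map(.data$L, function(l) {
          r_seq <- correlations$r[correlations$L == l]
          if (length(r_seq) >= config$segment_length) {
            segment_periodicity(r_seq,
                                segment_length = config$segment_length,
                                n_segments = config$n_segments,
                                seed = config$seed + l)
          } else {
            NULL
          }
        })
      )
  })
  report <- build_report(config, pair, profile, selected, networks,
                         correlations)
  run <- structure(
    list(
      pair = pair, scenarios = scenarios, correlations = correlations,
      overall = overall, profile = profile, modes = modes,
      selected = selected, networks = networks, report = report,
      config = config
    ),
    class = "acfm_run"
  )
  if (!is.null(output_dir)) {
    write_run_bundle(run, output_dir)
  }
  run
}

build_report <- function(config, pair, profile, selected, networks,
                         correlations) {
  per_network <- purrr::pmap(
    networks[c("L", "network", "power_law", "key_modes", "subgroups",
               "structural_holes", "paths", "spectral")],
    function(L, network, power_law, key_modes, subgroups, structural_holes,
             paths, spectral) {
      list(
        L = L,
        n_nodes = network$N,
        n_edges = network$E,
        total_weight = sum(network$edges$weight),
        power_law = if (is.null(power_law)) NULL else {
          list(a = power_law$a, b = power_law$b, r_squared = power_law$r_squared)
        },
        key_modes = key_modes,
        subgroups = if (nrow(subgroups)) {
          subgroups |>
            dplyr::mutate(members = purrr::map_chr(.data$members, paste,
                                                   collapse = " ")) |>
            dplyr::select("rank", "members", "internal_weight", "core_mode",
                          "category")
        } else {
          NULL
        },
        max_hierarchy = if (nrow(structural_holes)) {
          max(structural_holes$hierarchy, na.rm = TRUE)
        } else {
          NA
        },
        apl = paths$apl,
        diameter = paths$diameter,
        component_coverage = paths$coverage,
        distance_histogram = paths$histogram,
        modal_dominant_period = if (is.null(spectral)) NULL else spectral$modal_period
      )
    }
  )
  list(
    parameters = list(
      n_weeks = nrow(pair), l_max = config$l_max, window = config$window,
      omega = config$omega, cutoffs = config$cutoffs,
      g_size = config$g_size, sigma = config$sigma,
      n_select = config$n_select, segment_length = config$segment_length,
      seed = config$seed
    ),
    n_scenarios = 2L * config$l_max + 1L,
    mode_space_size = 5L^config$omega,
    n_undefined_windows = sum(correlations$undefined),
    symbol_profile = profile,
    selected_scenarios = selected$L,
    networks = per_network
  )
}

write_run_bundle <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  readr::write_csv(run$pair[c("date", "index_value", "deaths")], p("pair.csv"))
  readr::write_csv(
    dplyr::select(run$correlations, "L", "window", "window_start", "r",
                  "undefined", "symbol"),
    p("correlations.csv")
  )
  readr::write_csv(run$modes, p("modes.csv"))
  readr::write_csv(run$profile, p("symbol_profile.csv"))
  readr::write_csv(run$overall, p("overall_correlations.csv"))
  purrr::pwalk(run$networks[c("L", "network")], function(L, network) {
    tag <- sprintf("network_L%+03d", L)
    write_mode_network(network,
                       graphml_path = p(paste0(tag, ".graphml")),
                       edgelist_path = p(paste0(tag, "_edges.csv")))
  })
  spectral_rows <- purrr::pmap_dfr(
    run$networks[c("L", "spectral")],
    function(L, spectral) {
      if (is.null(spectral)) {
        return(tibble())
      }
      dplyr::mutate(spectral$segments, L = L, .before = 1)
    }
  )
  if (nrow(spectral_rows)) {
    readr::write_csv(spectral_rows, p("spectral_summary.csv"))
  }
  hole_rows <- purrr::pmap_dfr(
    run$networks[c("L", "structural_holes")],
    function(L, structural_holes) dplyr::mutate(structural_holes, L = L, .before = 1)
  )
  readr::write_csv(hole_rows, p("structural_holes.csv"))
  jsonlite::write_json(run$report, p("report.json"),
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.acfm_run <- function(x, ...) {
  cat(sprintf(
    "<acfm_run> n = %d weeks, %d scenarios, %d selected networks (L = %s)\n",
    nrow(x$pair), nrow(x$profile), nrow(x$networks),
    paste(sort(x$networks$L), collapse = ", ")
  ))
  invisible(x)
}
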