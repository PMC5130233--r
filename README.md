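# acfmnet

Fluctuation-mode network analysis of the lagged correlation between a pair
of weekly time series — a continuous economic index and a nonnegative
event-count series (the motivating case: a weekly coal-price index against
weekly coal-mining accident deaths, where price declines may surface as
excess deaths only weeks later).

The pipeline answers: *at which lag are the two series coupled, and how does
that coupling fluctuate?* It does so by turning the correlation dynamics
into a directed weighted network:

1. **Lag scan** — scenario $L \in [-16, 16]$ pairs $(x_{t+L}, y_t)$;
   33 scenarios, each keeping $n - |L|$ pairs. Positive $L$ means the index
   observation trails the count observation.
2. **Sliding-window correlation** — Pearson $r$ over step-1 windows of
   $T = 3$ weeks: $(n - |L|) - T + 1$ coefficients per scenario.
3. **Symbolization** — five levels
   A $[0.8,1]$, B $[0.3,0.8)$, C $(-0.3,0.3)$, D $(-0.8,-0.3]$,
   E $[-1,-0.8]$.
4. **Coarse-graining** — step-1 windows of $\omega = 3$ symbols form
   fluctuation modes (`CDB`, `DBD`, ...; at most $5^3 = 125$).
5. **Mode networks** — consecutive modes become weighted directed edges;
   the 9 scenarios least dominated by the no-correlation symbol are kept.
6. **Topology & spectra** — node strength $ns_i = \sum_j w_{ij}$ (in +
   out), Markov transition probabilities, log–log OLS power-law fit
   $P(k) = a k^{-b}$, k-plex subgroups ($g = 3$, $\sigma = 2$) with
   clustering-coefficient core modes, Burt constraint
   $C_{ij} = (p_{ij} + \sum_q p_{iq} p_{qj})^2$ and Coleman–Theil
   hierarchy $H_i$, largest-component average path length, and
   periodograms of 50-week correlation segments.

A seeded synthetic generator (`synth_config()` / `simulate_pair()`)
produces index/count pairs with known coupling lag, sign, strength and
periodicity, so every stage is testable without external data. See the
methods vignette (`vignettes/acfm-networks.Rmd`) for the model, parameter
meanings and design decisions.

## Worked example

```r
library(acfmnet)

# a pair with a strong negative coupling injected at lag 10
cfg <- synth_config(n_weeks = 176, seed = 42, coupling_lag = 10,
                    coupling_sign = -1L, coupling_strength = 1.2,
                    dispersion = Inf)
pair  <- simulate_pair(cfg)
scen  <- build_scenarios(pair, l_max = 16)            # 33 lag scenarios
cors  <- symbolize(correlation_sequences(scen, window = 3))
prof  <- symbol_profile(cors)
prof[which.max(prof$D + prof$E), ]
#>       L window      A      B     C     D     E n_symbols
#> 1   -10      3 0.0671 0.0549 0.159 0.366 0.354       164
```

The strong/weak-negative share peaks at scenario `L = -10`: the scan
recovers the injected lag (counts respond to index changes 10 weeks
earlier), with 72% of windows in the negative levels.

```r
modes <- mode_sequences(cors, omega = 3)
net   <- build_mode_network(modes$mode[modes$L == -10],
                            L = -10L, window = 3L, omega = 3L)
net
#> <mode_network> N = 58 nodes, E = 100 edges, total weight = 161 (L = -10, T = 3, omega = 3)

key_modes(net, top_k = 3)
#>    rank mode  strength  share cumulative_share
#> 1     1 DED         28 0.0870           0.0870
#> 2     2 DDE         18 0.0559           0.143
#> 3     3 EDC         18 0.0559           0.199

fit_power_law(net)
#> <powerlaw_fit> P(k) = 0.9375 * k^-1.333  (R^2 = 0.832, 11 distinct degrees)

path_statistics(net)
#> <path_statistics> APL = 3.506, diameter = 8, largest component 58/58 nodes (100%)

enumerate_kplex(net, g_size = 3, sigma = 2, top_k = 3)$category
#> [1] "weak negative correlation" "weak negative correlation"
#> [3] "weak negative correlation"
```

A handful of negative-correlation modes (`DED`, `DDE`, ...) carry the bulk
of the transition mass, and the top cohesive subgroups are all
negative-correlation triples — the network view of a persistent, fluctuating
negative coupling. `run_pipeline(pipeline_config(...), output_dir = "out")`
executes all stages at once and writes tidy CSVs, GraphML networks and a
JSON report; `autoplot()` / `plot_*()` functions draw each result type, and
`tidy()` / `glance()` give broom-style summaries. A thin command-line
wrapper lives in `inst/cli/acfm.R` (`simulate` and `run` subcommands).

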