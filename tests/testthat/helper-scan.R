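# Shared end-to-end scan helpers for the recovery studies.

# Lag at which the strong-negative symbol proportion (D + E) peaks.
strong_negative_argmax <- function(pair, l_max = 16, window = 3) {
  scen <- acfmnet::build_scenarios(pair, l_max = l_max)
  cors <- suppressMessages(
    acfmnet::symbolize(acfmnet::correlation_sequences(scen, window = window))
  )
  prof <- acfmnet::symbol_profile(cors)
  prof$L[which.max(prof$D + prof$E)]
}

# Strong coupling for recovery studies: a 1% weekly index move scales the
# count intensity e^2-fold, dominating Poisson count noise.
strong_coupling_config <- function(lag, seed, period_weeks = NULL) {
  acfmnet::synth_config(
    n_weeks = 176, seed = seed,
    coupling_lag = lag, coupling_sign = -1L, coupling_strength = 2,
    dispersion = Inf, period_weeks = period_weeks
  )
}

# Correlation-coefficient sequence of one scenario, end to end.
scenario_r_sequence <- function(pair, L, window = 3) {
  scen <- acfmnet::build_scenarios(pair, l_max = abs(L))
  cors <- suppressMessages(acfmnet::correlation_sequences(scen, window = window))
  cors$r[cors$L == L]
}
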