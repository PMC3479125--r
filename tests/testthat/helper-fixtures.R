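# Shared fixtures: small presets and hand-built traces/events, all generated
# in code.

# minimal two-state channel for kinetics-focused tests
toy_preset <- function(g = c(S0 = 4.0, S1 = 2.0),
                       dwell = c(S0 = 0.05, S1 = 0.05),
                       noise_sd_pA = 0, conductance_sd_nS = 0, ...) {
  channel_preset("toy", states = g, mean_dwell_s = dwell,
                 transition_weights = list(S0 = c(S1 = 1), S1 = c(S0 = 1)),
                 noise_sd_pA = noise_sd_pA,
                 conductance_sd_nS = conductance_sd_nS, ...)
}

# build a current_trace from raw vectors
make_trace <- function(current_pA, voltage_mV, fs_Hz) {
  structure(list(fs_Hz = fs_Hz, current_pA = current_pA,
                 voltage_mV = voltage_mV,
                 meta = list(preset = "manual", noise_sd_pA = 0),
                 paths = NULL),
            class = "current_trace")
}

# hand-built classified event table (one region unless stated)
make_events <- function(states, durations, conductance_nS, voltage_mV = 40,
                        region = 1) {
  end <- cumsum(durations)
  start <- end - durations
  data.frame(start_s = start, end_s = end, duration_s = durations,
             voltage_mV = voltage_mV,
             mean_current_pA = conductance_nS * voltage_mV,
             delta_current_pA = conductance_nS * voltage_mV,
             conductance_nS = conductance_nS,
             n_samples = round(durations * 200), region = region,
             state = states)
}

# overlap in seconds between sojourns (rows of a state_path) and the time
# windows of protocol steps selected by `step_sel`
path_overlap_s <- function(path, protocol, step_sel) {
  ends <- cumsum(protocol$duration_s)
  starts <- ends - protocol$duration_s
  tot <- 0
  for (j in which(step_sel)) {
    tot <- tot + sum(pmax(0, pmin(path$end_s, ends[j]) -
                            pmax(path$start_s, starts[j])))
  }
  tot
}
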