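# Semi-Markov gating simulator.
#
# The gating process is a semi-Markov chain: the channel stays in a state for
# an exponentially distributed sojourn with the preset's per-state mean, then
# jumps to a successor drawn from the preset's categorical transition
# weights. For polarity-asymmetric presets, transitions out of the open state
# S0 are suppressed (the S0 sojourn simply continues) whenever the applied
# voltage's sign differs from the preset orientation, and a closed sojourn is
# forced back to S0 the moment the voltage leaves the closing polarity.

#' Simulate a gating state path
#'
#' Realizes the semi-Markov gating process of a channel preset over the
#' duration of a voltage protocol. The path is truncated exactly at the
#' protocol end, so sojourn times always sum to the protocol duration.
#'
#' @param preset a `channel_preset`.
#' @param protocol a `voltage_protocol` (needed for polarity-asymmetric
#'   presets; the kinetics themselves are voltage-independent).
#' @param seed integer seed; fixed seed gives an identical path.
#' @param initial_state starting state label (default `"S0"`).
#' @return data.frame of class `state_path` with columns `state`, `start_s`,
#'   `end_s`: contiguous, non-overlapping sojourns covering the protocol, with
#'   consecutive sojourns in different states.
#' @export
simulate_state_path <- function(preset, protocol, seed = 1L,
                                initial_state = "S0") {
  protocol <- as_voltage_protocol(protocol)
  labels <- names(preset$states)
  if (!initial_state %in% labels)
    stop("initial_state must be a state of the preset")
  total <- attr(protocol, "total_s")
  starts <- .protocol_starts(protocol)
  sgn <- sign(protocol$voltage_mV)
  orient <- preset$orientation
  asym <- preset$asymmetric

  # first time >= t at which the polarity no longer permits closure
  next_nonclosing <- function(t) {
    i <- max(1, min(nrow(protocol), findInterval(t, starts)))
    if (sgn[i] != orient) return(t)
    while (i <= nrow(protocol) && sgn[i] == orient) i <- i + 1
    if (i > nrow(protocol)) Inf else starts[i]
  }
  sign_at <- function(t) {
    i <- max(1, min(nrow(protocol), findInterval(t, starts)))
    sgn[i]
  }

  local_seed(seed, {
    st <- character(0); s0 <- numeric(0); s1 <- numeric(0)
    state <- initial_state
    soj_start <- 0
    t <- 0
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > 5e6L)
        stop("state path exceeded 5e6 transitions; check dwell means vs protocol length")
      succ_w <- preset$transition_weights[[state]]
      if (length(succ_w) == 0) { # single-state channel: one sojourn
        st <- c(st, state); s0 <- c(s0, soj_start); s1 <- c(s1, total)
        break
      }
      t_end <- t + stats::rexp(1, rate = 1 / preset$mean_dwell_s[[state]])
      forced <- NULL
      if (asym && state != "S0") {
        t_nc <- next_nonclosing(t)
        if (t_end > t_nc) { t_end <- t_nc; forced <- "S0" }
      }
      if (t_end >= total) {
        st <- c(st, state); s0 <- c(s0, soj_start); s1 <- c(s1, total)
        break
      }
      succ <- if (is.null(forced)) {
        nm <- names(succ_w)
        if (length(nm) == 1) nm else sample(nm, 1, prob = succ_w)
      } else forced
      if (asym && succ != "S0" && sign_at(t_end) != orient) {
        # closure suppressed under this polarity: the sojourn continues
        t <- t_end
        next
      }
      st <- c(st, state); s0 <- c(s0, soj_start); s1 <- c(s1, t_end)
      state <- succ
      soj_start <- t <- t_end
    }
    out <- data.frame(state = st, start_s = s0, end_s = s1,
                      stringsAsFactors = FALSE)
    class(out) <- c("state_path", "data.frame")
    attr(out, "preset") <- preset$name
    attr(out, "total_s") <- total
    out
  })
}

#' Render a current trace from a state path
#'
#' Ohmic rendering: I(t) = g(state(t)) * V(t) + noise, with g in nS and V in
#' mV so that I is in pA. Each sojourn's conductance is the state conductance
#' plus an optional Gaussian per-sojourn scatter (`conductance_sd_nS`)
#' reproducing the event-to-event spread of measured amplitudes. Noise and
#' scatter use independent streams derived from `seed`, so the same path can
#' be re-rendered with a different noise realization.
#'
#' @param path a `state_path`.
#' @param preset the `channel_preset` that generated the path.
#' @param protocol the `voltage_protocol`.
#' @param fs_Hz sampling rate, Hz (acquisition rate; decimate afterwards).
#' @param seed integer seed for scatter and noise.
#' @param noise_sd_pA noise standard deviation; defaults to the preset's.
#' @param conductance_sd_nS per-sojourn conductance scatter; defaults to the
#'   preset's.
#' @param insertion_delay_s samples before this time carry zero channel
#'   current (pre-insertion baseline).
#' @return object of class `current_trace`: list with `fs_Hz`, `current_pA`,
#'   `voltage_mV`, `meta`.
#' @export
render_current <- function(path, preset, protocol, fs_Hz = 5000, seed = 1L,
                           noise_sd_pA = preset$noise_sd_pA,
                           conductance_sd_nS = preset$conductance_sd_nS,
                           insertion_delay_s = 0) {
  stopifnot(fs_Hz > 0)
  protocol <- as_voltage_protocol(protocol)
  total <- attr(protocol, "total_s")
  n <- round(fs_Hz * total)
  tm <- (seq_len(n) - 0.5) / fs_Hz
  V <- protocol_voltage(protocol, tm)
  g_soj <- .sojourn_conductances(path, preset, derive_seed(seed, 1),
                                 conductance_sd_nS)
  idx <- findInterval(tm, path$start_s)
  idx[idx < 1] <- 1
  g_t <- g_soj[idx]
  if (insertion_delay_s > 0) g_t[tm < insertion_delay_s] <- 0
  current <- g_t * V
  if (noise_sd_pA > 0) {
    current <- current +
      local_seed(derive_seed(seed, 2), stats::rnorm(n, 0, noise_sd_pA))
  }
  .current_trace(fs_Hz, current, V,
                 meta = list(preset = preset$name, seed = seed,
                             noise_sd_pA = noise_sd_pA,
                             conductance_sd_nS = conductance_sd_nS,
                             n_channels = 1),
                 paths = list(path))
}

.sojourn_conductances <- function(path, preset, seed, conductance_sd_nS) {
  g <- unname(preset$states[path$state])
  if (conductance_sd_nS > 0) {
    jitter <- local_seed(seed, stats::rnorm(nrow(path), 0, conductance_sd_nS))
    g <- pmax(g + jitter, 0.05)
  }
  g
}

.current_trace <- function(fs_Hz, current_pA, voltage_mV, meta, paths = NULL) {
  structure(list(fs_Hz = fs_Hz, current_pA = current_pA,
                 voltage_mV = voltage_mV, meta = meta, paths = paths),
            class = "current_trace")
}

#' Simulate a complete bilayer recording
#'
#' End-to-end convenience wrapper: simulates one gating path per channel
#' (up to 5 channels, all with the same orientation, reflecting auto-directed
#' insertion), renders the summed Ohmic currents, adds acquisition noise
#' once, and optionally prepends a channel-free baseline stretch and
#' decimates to the analysis rate. All randomness derives from `seed`.
#'
#' @param preset a `channel_preset` or preset name.
#' @param protocol a `voltage_protocol`.
#' @param fs_Hz acquisition sampling rate (default 5000 Hz).
#' @param seed master seed.
#' @param n_channels number of independently gating channels (1..5).
#' @param baseline_lead_s channel-free time at the start of the record, used
#'   by baseline estimation (the channels insert after this delay).
#' @param decimate_to_Hz if non-NULL, block-average to this rate.
#' @return a `current_trace`; the generating `state_path`s are kept in
#'   `$paths` for oracle comparisons.
#' @export
simulate_trace <- function(preset, protocol, fs_Hz = 5000, seed = 1L,
                           n_channels = 1, baseline_lead_s = 0,
                           decimate_to_Hz = NULL) {
  preset <- as_channel_preset(preset)
  protocol <- as_voltage_protocol(protocol)
  if (n_channels < 1 || n_channels > 5)
    stop("n_channels must be between 1 and 5")
  total <- attr(protocol, "total_s")
  n <- round(fs_Hz * total)
  tm <- (seq_len(n) - 0.5) / fs_Hz
  V <- protocol_voltage(protocol, tm)
  G <- numeric(n)
  paths <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    p <- simulate_state_path(preset, protocol, derive_seed(seed, 1000 + ch))
    g_soj <- .sojourn_conductances(p, preset, derive_seed(seed, 2000 + ch),
                                   preset$conductance_sd_nS)
    idx <- findInterval(tm, p$start_s)
    idx[idx < 1] <- 1
    G <- G + g_soj[idx]
    paths[[ch]] <- p
  }
  if (baseline_lead_s > 0) G[tm < baseline_lead_s] <- 0
  current <- G * V
  if (preset$noise_sd_pA > 0) {
    current <- current +
      local_seed(derive_seed(seed, 3000),
                 stats::rnorm(n, 0, preset$noise_sd_pA))
  }
  trace <- .current_trace(fs_Hz, current, V,
                          meta = list(preset = preset$name, seed = seed,
                                      noise_sd_pA = preset$noise_sd_pA,
                                      conductance_sd_nS = preset$conductance_sd_nS,
                                      n_channels = n_channels,
                                      baseline_lead_s = baseline_lead_s),
                          paths = paths)
  if (!is.null(decimate_to_Hz)) trace <- decimate_trace(trace, decimate_to_Hz)
  trace
}

#' Decimate a current trace by block averaging
#'
#' Non-overlapping block means reduce the acquisition rate (e.g. 5 kHz) to
#' the analysis rate (e.g. 200 Hz); the voltage channel is decimated
#' identically. The rate ratio must be an integer.
#'
#' @param trace a `current_trace`.
#' @param target_fs_Hz target rate; `fs_Hz / target_fs_Hz` must be integer.
#' @return decimated `current_trace`.
#' @export
decimate_trace <- function(trace, target_fs_Hz) {
  ratio <- trace$fs_Hz / target_fs_Hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fs_Hz (", trace$fs_Hz, ") is not an integer multiple of the target rate (",
         target_fs_Hz, ")")
  ratio <- as.integer(round(ratio))
  n <- length(trace$current_pA)
  keep <- (n %/% ratio) * ratio
  if (keep < n)
    warning(n - keep, " trailing samples dropped (partial block)")
  blockmean <- function(x) {
    .colMeans(x[seq_len(keep)], ratio, keep %/% ratio)
  }
  meta <- trace$meta
  meta$decimated_from_Hz <- trace$fs_Hz
  .current_trace(target_fs_Hz, blockmean(trace$current_pA),
                 blockmean(trace$voltage_mV), meta, paths = trace$paths)
}

#' @export
print.current_trace <- function(x, ...) {
  n <- length(x$current_pA)
  cat("<current_trace>", n, "samples @", x$fs_Hz, "Hz (",
      round(n / x$fs_Hz, 3), "s )\n")
  cat("  preset:", x$meta$preset %||% "?", " channels:",
      x$meta$n_channels %||% 1, " noise sd:", x$meta$noise_sd_pA, "pA\n")
  invisible(x)
}

#' Trace sample times
#' @param trace a `current_trace`.
#' @return sample midpoint times in seconds.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$current_pA) - 0.5) / trace$fs_Hz
}
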