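# Gating simulator: presets, semi-Markov paths, Ohmic rendering, decimation.

test_that("registered presets carry the reported state parameters", {
  p <- build_preset("native")
  expect_equal(state_conductance(p, "S0"), 3.94)
  expect_equal(state_conductance(p, "S1"), 2.61)
  expect_equal(state_conductance(p, "S2A"), 2.03)
  expect_equal(state_conductance(p, "S2B"), 1.48)
  expect_equal(unname(p$mean_dwell_s[c("S0", "S1", "S2A", "S2B")]),
               c(27.40, 2.92, 2.45, 2.45))
  expect_false(p$asymmetric)

  d <- build_preset("delta21")
  expect_equal(names(d$states), "S0")
  expect_equal(state_conductance(d, "S0"), 4.00)

  v <- build_preset("V3C-K119C_ox")
  expect_true(v$asymmetric)
  expect_equal(v$orientation, 1L)

  expect_error(build_preset("nope"), "registered presets")
  expect_error(state_conductance(d, "S1"), "no state")
})

test_that("preset invariants are enforced", {
  expect_error(
    channel_preset("bad", states = c(S0 = 4, S1 = 2),
                   mean_dwell_s = c(S0 = 1, S1 = 1),
                   transition_weights = list(S0 = c(S1 = 0.5), S1 = c(S0 = 1))),
    "sum to 1")
  expect_error(
    channel_preset("bad", states = c(S0 = 4, S1 = 2),
                   mean_dwell_s = c(S0 = 1, S1 = -1),
                   transition_weights = list(S0 = c(S1 = 1), S1 = c(S0 = 1))),
    "positive")
  expect_error(
    channel_preset("bad", states = c(S0 = 4, S1 = 2),
                   mean_dwell_s = c(S0 = 1, S1 = 1),
                   transition_weights = list(S0 = c(S1 = 1), S1 = c(S0 = 1)),
                   asymmetric = TRUE, orientation = 0),
    "orientation")
})

test_that("dwell rescaling pins the theoretical overall mean sojourn", {
  p <- build_preset("native")
  # visit frequencies of the embedded chain: S0 is every second visit
  pi_hat <- visit_frequencies(p)
  expect_equal(unname(pi_hat["S0"]), 0.5, tolerance = 1e-9)
  expect_equal(sum(pi_hat), 1, tolerance = 1e-12)
  p2 <- rescale_dwell_means(p, 10.34)
  expect_equal(theoretical_mean_sojourn(p2), 10.34, tolerance = 1e-9)
  # conductances untouched
  expect_equal(p2$states, p$states)
})

test_that("state paths conserve protocol duration and alternate states", {
  p <- build_preset("native")
  proto <- step_protocol(c(40, -40), step_s = 60, cycles = 2)
  path <- simulate_state_path(p, proto, seed = 5)
  expect_equal(path$start_s[1], 0)
  expect_equal(path$end_s[nrow(path)], attr(proto, "total_s"))
  expect_equal(path$start_s[-1], path$end_s[-nrow(path)])  # contiguous
  expect_true(all(path$state[-1] != path$state[-nrow(path)]))
  # determinism
  expect_identical(path, simulate_state_path(p, proto, seed = 5))
  expect_false(identical(path, simulate_state_path(p, proto, seed = 6)))
})

test_that("a single-state preset yields one sojourn spanning the protocol", {
  path <- simulate_state_path(build_preset("delta21"),
                              voltage_protocol(30, 40), seed = 1)
  expect_equal(nrow(path), 1)
  expect_equal(path$state, "S0")
  expect_equal(path$end_s - path$start_s, 30)
})

test_that("asymmetric gating closes under one polarity only", {
  p <- build_preset("V3C-K119C_ox")  # orientation +1: closure when V > 0
  # only the non-closing polarity applied: path stays open
  neg <- voltage_protocol(300, -40)
  path_neg <- simulate_state_path(p, neg, seed = 2)
  expect_equal(unique(path_neg$state), "S0")

  # both polarities: closed time under V < 0 must be exactly zero
  proto <- step_protocol(c(-40, 40), step_s = 60, cycles = 3)
  path <- simulate_state_path(p, proto, seed = 3)
  closed <- path[path$state != "S0", , drop = FALSE]
  expect_gt(nrow(closed), 0)
  expect_equal(path_overlap_s(closed, proto, proto$voltage_mV < 0), 0)
})

test_that("sojourn durations follow the preset's exponential dwell law", {
  # sample-mean recovery: ~10,000 S0 sojourns at mean 10 s
  p <- toy_preset(dwell = c(S0 = 10, S1 = 0.01))
  proto <- voltage_protocol(101000, 40)
  path <- simulate_state_path(p, proto, seed = 11)
  dur <- with(path[path$state == "S0" & path$end_s < attr(proto, "total_s"), ],
              end_s - start_s)
  expect_gt(length(dur), 9000)
  se <- 10 / sqrt(length(dur))
  expect_lt(abs(mean(dur) - 10), 3 * se)

  # distributional check: one-sample KS against Exponential(mean)
  p2 <- toy_preset(dwell = c(S0 = 0.05, S1 = 0.05))
  proto2 <- voltage_protocol(600, 40)
  path2 <- simulate_state_path(p2, proto2, seed = 12)
  dur2 <- with(path2[path2$state == "S0" & path2$end_s < 600, ],
               end_s - start_s)
  expect_gt(length(dur2), 5000)
  ks <- suppressWarnings(stats::ks.test(dur2, "pexp", rate = 1 / 0.05))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering is Ohmic, in pA, and seed-reproducible", {
  p <- channel_preset("mono", states = c(S0 = 3.94),
                      mean_dwell_s = c(S0 = 1),
                      transition_weights = list(S0 = numeric(0)),
                      noise_sd_pA = 0, conductance_sd_nS = 0)
  proto <- voltage_protocol(2, 40)
  path <- simulate_state_path(p, proto, seed = 1)
  tr <- render_current(path, p, proto, fs_Hz = 1000, seed = 1,
                       noise_sd_pA = 0, conductance_sd_nS = 0)
  expect_true(all(tr$current_pA == 3.94 * 40))  # 157.6 pA, exactly

  proto0 <- voltage_protocol(2, 0)
  tr0 <- render_current(path, p, proto0, fs_Hz = 1000, seed = 1,
                        noise_sd_pA = 0, conductance_sd_nS = 0)
  expect_equal(mean(tr0$current_pA), 0)

  # noise sd recovery at n = 1e5 within 2 percent
  trn <- render_current(path, p, voltage_protocol(100, 0), fs_Hz = 1000,
                        seed = 4, noise_sd_pA = 2, conductance_sd_nS = 0)
  expect_lt(abs(sd(trn$current_pA) - 2) / 2, 0.02)

  # determinism: identical seeds give identical traces
  trn2 <- render_current(path, p, voltage_protocol(100, 0), fs_Hz = 1000,
                         seed = 4, noise_sd_pA = 2, conductance_sd_nS = 0)
  expect_identical(trn$current_pA, trn2$current_pA)
})

test_that("decimation takes exact non-overlapping block means", {
  p <- build_preset("delta21", noise_sd_pA = 0, conductance_sd_nS = 0)
  tr <- simulate_trace(p, voltage_protocol(10, 40), fs_Hz = 5000, seed = 1)
  dec <- decimate_trace(tr, 200)
  expect_equal(length(dec$current_pA), length(tr$current_pA) / 25)
  expect_true(all(dec$current_pA == tr$current_pA[1]))  # constant trace

  # alternating +1/-1 pA, block 25: compare to brute-force block means
  x <- rep(c(1, -1), length.out = 5000)
  trx <- make_trace(x, rep(40, 5000), 5000)
  decx <- decimate_trace(trx, 200)
  brute <- vapply(seq_len(200), function(b) mean(x[(25 * (b - 1) + 1):(25 * b)]),
                  numeric(1))
  expect_equal(decx$current_pA, brute)
  expect_true(all(abs(decx$current_pA) == 0.04))

  expect_error(decimate_trace(trx, 300), "integer multiple")
})

test_that("multi-channel traces sum independent channel currents", {
  p <- build_preset("delta21", noise_sd_pA = 0, conductance_sd_nS = 0)
  proto <- voltage_protocol(2, 40)
  tr3 <- simulate_trace(p, proto, fs_Hz = 1000, seed = 9, n_channels = 3)
  expect_true(all(tr3$current_pA == 3 * 4.00 * 40))
  expect_error(simulate_trace(p, proto, n_channels = 6), "between 1 and 5")
})
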