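# Dwell-time statistics, fold changes, asymmetry detection.

test_that("dwell summary excludes censored sojourns and counts conserve", {
  # first (3 s) and last (2 s) sojourns are censored; two 10 s sojourns stay
  ev <- make_events(states = c("S1", "S0", "S1", "S0"),
                    durations = c(3, 10, 10, 2),
                    conductance_nS = c(2.61, 3.94, 2.61, 3.94))
  ds <- dwell_summary(ev)
  expect_equal(ds$overall$mean_s, 10)
  expect_equal(ds$overall$n, 2)
  expect_equal(sum(ds$per_state$n), ds$overall$n)
  # the censored leading S1 contributes to no state
  expect_equal(ds$per_state$n[ds$per_state$state == "S1"], 1)

  # all sojourns censored -> error
  ev2 <- make_events(c("S0", "S1"), c(5, 5), c(3.94, 2.61))
  expect_error(dwell_summary(ev2), "no uncensored")
})

test_that("adjacent same-state segments merge into one sojourn", {
  # spurious split inside one S0 sojourn (equal conductance) heals, but a
  # genuine state change between same-labelled segments does not merge
  ev <- make_events(states = c("S1", "S0", "S0", "S1", "S0"),
                    durations = c(1, 4, 6, 2, 1),
                    conductance_nS = c(2.61, 3.94, 3.945, 2.61, 3.94))
  ds <- dwell_summary(ev)
  s0 <- ds$per_state[ds$per_state$state == "S0", ]
  expect_equal(s0$n, 1)
  expect_equal(s0$mean_s, 10)
})

test_that("dwell estimates are invariant to trace order and recover truth", {
  p <- toy_preset(g = c(S0 = 3.94, S1 = 1.48), dwell = c(S0 = 2, S1 = 1),
                  noise_sd_pA = 2, conductance_sd_nS = 0)
  proto <- voltage_protocol(240, 40)
  ideals <- lapply(1:2, function(i) {
    tr <- simulate_trace(p, proto, fs_Hz = 1000, seed = derive_seed(8, i),
                         decimate_to_Hz = 200)
    idealize_trace(tr, refs = p$states, baseline_pA = 0)
  })
  a <- dwell_summary(ideals)
  b <- dwell_summary(rev(ideals))
  expect_equal(a$overall$mean_s, b$overall$mean_s)
  expect_equal(a$per_state[order(a$per_state$state), c("mean_s", "n")],
               b$per_state[order(b$per_state$state), c("mean_s", "n")])

  # parameter recovery within 3 SEM at n >= 100 sojourns per state
  for (st in c("S0", "S1")) {
    row <- a$per_state[a$per_state$state == st, ]
    expect_gt(row$n, 60)
    expect_lt(abs(row$mean_s - p$mean_dwell_s[[st]]), 3 * row$sem_s)
  }
})

test_that("fold changes reproduce the reporting conventions", {
  expect_equal(fold_change(1836.60, 10.34, "ten"), 180)
  expect_equal(fold_change(36.70, 3.61, "integer"), 10)
  expect_equal(fold_change(2.34, 1.70, "tenth"), 1.4)
  expect_equal(fold_change(7, 7), 1.0)
  x <- 13.7; y <- 3.1
  expect_equal(fold_change(x, y) * fold_change(y, x), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("asymmetry detection matches the generator's orientation flag", {
  proto <- step_protocol(c(-40, 40), step_s = 60, cycles = 2)
  run_preset <- function(preset, seed) {
    tr <- simulate_trace(preset, proto, fs_Hz = 1000, seed = seed,
                         baseline_lead_s = 2, decimate_to_Hz = 200)
    idealize_trace(tr, refs = preset$states)
  }

  pv <- build_preset("V3C-K119C_ox")
  rep_v <- detect_asymmetry(run_preset(pv, 3))
  expect_true(rep_v$asymmetric)
  expect_equal(rep_v$inferred_orientation, pv$orientation)
  expect_lt(rep_v$closed_fraction_neg, 0.005)
  expect_gt(rep_v$closed_fraction_pos, 0.02)

  pn <- rescale_dwell_means(build_preset("native"), 5)
  rep_n <- detect_asymmetry(run_preset(pn, 4))
  expect_false(rep_n$asymmetric)

  # constitutively open channel: no closure at either polarity
  pd <- build_preset("delta21")
  rep_d <- detect_asymmetry(run_preset(pd, 5))
  expect_false(rep_d$asymmetric)
  expect_true(is.na(rep_d$inferred_orientation))

  # single-polarity data are not interpretable
  tr1 <- simulate_trace(pn, voltage_protocol(60, 40), fs_Hz = 1000, seed = 6,
                        baseline_lead_s = 2, decimate_to_Hz = 200)
  expect_error(detect_asymmetry(idealize_trace(tr1, refs = pn$states)),
               "both voltage polarities")
})
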