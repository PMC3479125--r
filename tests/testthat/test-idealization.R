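# Idealization: baseline, change-point segmentation, state classification.

test_that("baseline is recovered exactly on clean traces and offsets", {
  p <- build_preset("native", noise_sd_pA = 0, conductance_sd_nS = 0)
  tr <- simulate_trace(p, voltage_protocol(30, 40), fs_Hz = 200, seed = 2,
                       baseline_lead_s = 3)
  expect_equal(estimate_baseline(tr), 0)
  tr$current_pA <- tr$current_pA + 5
  expect_equal(estimate_baseline(tr), 5)
})

test_that("baseline falls back (with a warning) on degenerate traces", {
  trz <- make_trace(rep(1.5, 400), rep(0, 400), 200)
  expect_warning(b <- estimate_baseline(trz), "all-zero-voltage")
  expect_equal(as.numeric(b), 1.5)
  expect_true(attr(b, "flagged"))

  # no baseline-level samples: lowest-conductance cluster is used, warned
  trh <- make_trace(rep(1.48 * 40, 400), rep(40, 400), 200)
  expect_warning(bh <- estimate_baseline(trh), "lowest-conductance")
  expect_equal(as.numeric(bh), 1.48 * 40)
})

test_that("noiseless level changes are segmented at exact boundaries", {
  x <- c(rep(157.6, 400), rep(104.4, 400))
  tr <- make_trace(x, rep(40, 800), 200)
  ideal <- segment_trace(tr, baseline_pA = 0)
  expect_equal(nrow(ideal$segments), 2)
  expect_equal(ideal$segments$start_s, c(0, 2))
  expect_equal(ideal$segments$end_s, c(2, 4))
  expect_equal(ideal$segments$mean_current_pA, c(157.6, 104.4))

  # constant trace: exactly one segment
  trc <- make_trace(rep(157.6, 400), rep(40, 400), 200)
  idc <- segment_trace(trc, baseline_pA = 0)
  expect_equal(nrow(idc$segments), 1)

  expect_error(segment_trace(make_trace(numeric(0), numeric(0), 200)),
               "empty")
})

test_that("zero-noise idealization recovers the generator's path exactly", {
  p <- build_preset("native", noise_sd_pA = 0, conductance_sd_nS = 0)
  proto <- voltage_protocol(120, 40)
  tr <- simulate_trace(p, proto, fs_Hz = 5000, seed = 7, decimate_to_Hz = 200)
  path <- tr$paths[[1]]
  ideal <- idealize_trace(tr, refs = p$states, baseline_pA = 0)
  seg <- ideal$segments

  # conservation: segment durations cover the analyzable region
  expect_equal(sum(seg$duration_s), 120)

  # every true sojourn longer than the minimum event duration is recovered
  # with boundaries within one analysis sample and the correct label
  long <- path[path$end_s - path$start_s >= 0.03, ]
  for (i in seq_len(nrow(long))) {
    mid <- (long$start_s[i] + long$end_s[i]) / 2
    j <- which(seg$start_s <= mid & seg$end_s > mid)
    expect_length(j, 1)
    expect_equal(seg$state[j], long$state[i])
    expect_lt(abs(seg$start_s[j] - long$start_s[i]),
              1 / 200 + 1e-9 + (i == 1) * 0)  # one sample at 200 Hz
    expect_lt(abs(seg$end_s[j] - long$end_s[i]), 1 / 200 + 1e-9)
  }
})

test_that("segment count matches the generator on a noisy native trace", {
  p <- build_preset("native")
  proto <- voltage_protocol(60, 40)
  tr <- simulate_trace(p, proto, fs_Hz = 5000, seed = 31,
                       decimate_to_Hz = 200)
  path <- tr$paths[[1]]
  n_true <- sum(path$end_s - path$start_s >= 0.025)
  ideal <- segment_trace(tr, baseline_pA = 0)
  expect_equal(nrow(ideal$segments), n_true)
})

test_that("classification windows, tie-breaks and fallbacks are correct", {
  refs <- build_preset("native")$states
  expect_equal(classify_state(3.94, refs), "S0")
  expect_equal(classify_state(2.61 * 1.05, refs), "S1")  # boundary inclusive
  expect_equal(classify_state(2.30, refs[c("S1", "S2A")]), "INTERMEDIATE")
  expect_equal(classify_state(0.10, refs), "BASELINE")
  # just below the BASELINE cutoff of the smallest reference: intermediate
  expect_equal(classify_state(1.48 * 0.91, refs), "INTERMEDIATE")
  expect_error(classify_state(1, refs, window = 0.6), "window")
})

test_that("classification is scale-consistent and window-monotone", {
  refs <- c(S0 = 3.94, S1 = 2.61, S2A = 2.03, S2B = 1.48)
  gs <- seq(0.5, 4.5, by = 0.013)
  base <- classify_state(gs, refs)
  for (f in c(0.1, 3, 40)) {
    expect_identical(classify_state(gs * f, refs * f), base)
  }
  wide <- classify_state(gs, refs, window = 0.08)
  labeled <- base %in% names(refs)
  expect_false(any(wide[labeled] == "INTERMEDIATE"))
})
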