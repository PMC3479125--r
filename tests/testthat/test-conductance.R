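# Ohm fits, amplitude histograms, Gaussian-mixture decomposition.

test_that("through-origin Ohm fit is exact on exactly linear events", {
  ev <- make_events(states = rep("S0", 6), durations = rep(1, 6),
                    conductance_nS = rep(3.94, 6),
                    voltage_mV = c(-40, -20, -10, 10, 20, 40))
  f <- ohm_fit(ev, "S0")
  expect_equal(f$conductance_nS, 3.94, tolerance = 1e-12)
  expect_equal(f$n, 6)
  expect_equal(f$n_voltages, 6)
  expect_false(f$fallback)

  # single voltage: mean conductance with fallback flag
  ev1 <- make_events(rep("S0", 3), rep(1, 3), c(3.9, 4.0, 3.8), 40)
  f1 <- ohm_fit(ev1, "S0")
  expect_true(f1$fallback)
  expect_equal(f1$conductance_nS, mean(c(3.9, 4.0, 3.8)))

  expect_error(ohm_fit(ev1, "S2B"), "no events")
})

test_that("Ohm fit recovers the generating conductance from noisy traces", {
  p <- build_preset("native")
  proto <- step_protocol(c(10, -10, 20, -20, 40, -40), step_s = 20)
  evs <- lapply(1:4, function(i) {
    tr <- simulate_trace(p, proto, fs_Hz = 5000, seed = derive_seed(21, i),
                         baseline_lead_s = 2, decimate_to_Hz = 200)
    idealize_trace(tr, refs = p$states, baseline_pA = 0)$segments
  })
  f <- ohm_fit(do.call(rbind, evs), "S0")
  expect_lt(abs(f$conductance_nS - 3.94), 3 * f$sem_nS)
})

test_that("histograms count conservatively with verified bin edges", {
  h <- closed_state_histogram(c(1.92, 1.93, 1.94), bin_width_nS = 0.1)
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$bin_left <= 1.92 & h$bin_right > 1.94], 3)

  set.seed(40)
  vals <- runif(500, 0.9, 2.8)
  h2 <- closed_state_histogram(vals, bin_width_nS = 0.05)
  expect_equal(sum(h2$count), 500)
  # brute-force oracle for every bin
  brute <- mapply(function(a, b) sum(vals > a & vals <= b),
                  h2$bin_left, h2$bin_right)
  brute[1] <- brute[1] + sum(vals == h2$bin_left[1])
  expect_equal(h2$count, unname(brute))

  # histogram linearity: adding events at an existing bin center
  vals3 <- c(vals, rep(h2$bin_mid[10], 7))
  h3 <- closed_state_histogram(vals3, bin_width_nS = 0.05)
  expect_equal(h3$count[10], h2$count[10] + 7)

  expect_error(closed_state_histogram(numeric(0)), "no closed events")
})

test_that("mixture fits recover known components and nest properly", {
  set.seed(101)
  uni <- rnorm(400, 2.0, 0.10)
  f1 <- fit_mixture(uni, k = 1)
  expect_lt(abs(f1$components$mean_nS - mean(uni)) / mean(uni), 0.02)

  bi <- c(rnorm(250, 2.03, 0.12), rnorm(250, 1.48, 0.12))
  f2 <- fit_mixture(bi, k = 2)
  expect_equal(f2$components$mean_nS[1], 2.03, tolerance = 0.05 / 2.03)
  expect_equal(f2$components$mean_nS[2], 1.48, tolerance = 0.05 / 1.48)
  expect_true(all(diff(f2$components$mean_nS) < 0))   # sorted by mean
  expect_equal(sum(f2$components$weight), 1, tolerance = 1e-6)

  # nesting: the two-component fit is never worse than one component
  for (s in 1:4) {
    set.seed(200 + s)
    vals <- switch(s %% 2 + 1,
                   rnorm(300, 2.0, 0.15),
                   c(rnorm(200, 2.2, 0.1), rnorm(120, 1.6, 0.1)))
    k1 <- fit_mixture(vals, 1)
    k2 <- fit_mixture(vals, 2)
    expect_gte(k2$r_squared + 1e-8, k1$r_squared)
  }

  expect_error(fit_mixture(rnorm(10), 2), "at least 30")
})

test_that("binned least-squares means agree with an EM oracle", {
  set.seed(77)
  vals <- c(rnorm(300, 2.03, 0.12), rnorm(150, 1.48, 0.12))
  ls_fit <- fit_mixture(vals, 2)
  suppressMessages(library(mclust))
  em <- Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  em_means <- sort(as.numeric(em$parameters$mean), decreasing = TRUE)
  expect_equal(ls_fit$components$mean_nS, em_means, tolerance = 0.03)
})

test_that("two-stage decomposition resolves S1, S2A and S2B", {
  set.seed(31)
  vals <- c(rnorm(386, 2.61, 0.12), rnorm(224, 2.03, 0.12),
            rnorm(70, 1.48, 0.12))
  d <- decompose_closed_states(vals)
  cmp <- d$components
  expect_setequal(cmp$state, c("S1", "S2A", "S2B"))
  expect_lt(abs(cmp$mean_nS[cmp$state == "S1"] - 2.61), 0.08)
  expect_lt(abs(cmp$mean_nS[cmp$state == "S2A"] - 2.03), 0.08)
  expect_lt(abs(cmp$mean_nS[cmp$state == "S2B"] - 1.48), 0.08)
  expect_true(all(cmp$n_assigned > 0))
  expect_equal(sum(cmp$n_assigned), 680)
  expect_true(d$s2a_s2b_count_ratio > 1)
  expect_true(is.finite(d$s2a_s2b_area_ratio))
  # both closed-state location summaries are reported
  expect_true(is.finite(d$sample_mean_nS))
  expect_true(is.finite(d$single_gaussian$components$mean_nS[1]))
})

test_that("stage-2 fit quality is high at the reported sample size", {
  set.seed(52)
  vals <- c(rnorm(224, 2.03, 0.12), rnorm(70, 1.48, 0.12))
  f <- fit_mixture(vals, 2, fit_range_nS = c(0.80, 2.20))
  expect_gte(f$r_squared, 0.9)
})

test_that("degenerate closed samples yield a single flagged component", {
  expect_warning(d <- decompose_closed_states(rep(2.0, 120)), "degenerate")
  expect_equal(nrow(d$components), 1)
  expect_equal(d$components$mean_nS, 2.0)
})

test_that("percent-of-open follows half-up integer rounding", {
  expect_identical(percent_of_open(2.61, 3.94), 66L)
  expect_identical(percent_of_open(1.90, 3.94), 48L)
  expect_identical(percent_of_open(2.5, 2.5), 100L)
  expect_error(percent_of_open(1, 0), "positive")
})
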