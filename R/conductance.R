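# Conductance estimation across voltages (Ohm plots) and Gaussian-mixture
# decomposition of the closed-state amplitude histogram.
#
# The mixture is fitted by least squares on the binned histogram (the
# Origin-style workflow used for the original amplitude analysis), not by
# EM; the binned fit defines the reported component parameters and R^2.

#' Through-origin Ohm fit for one state
#'
#' Regresses the per-voltage mean baseline-subtracted current on voltage with
#' no intercept (an ohmic channel passes through the origin), weighting each
#' voltage by its number of events. The slope is the state conductance in nS.
#' With events at a single voltage the mean per-event conductance is returned
#' and flagged as a fallback.
#'
#' @param events event data.frame (from an [idealization]'s `segments`) with
#'   columns `state`, `voltage_mV`, `delta_current_pA`, `conductance_nS`.
#' @param state state label to fit.
#' @param free_intercept also report a free-intercept diagnostic fit.
#' @return object of class `ohm_fit`: `state`, `conductance_nS`, `sem_nS`,
#'   `n`, `n_voltages`, `per_voltage` (data.frame), `fallback`, `low_n`,
#'   optionally `intercept_diagnostic`.
#' @export
ohm_fit <- function(events, state, free_intercept = FALSE) {
  ev <- events[!is.na(events$state) & events$state == state, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events with state '", state, "'")
  agg <- stats::aggregate(delta_current_pA ~ voltage_mV, data = ev, FUN = mean)
  cnt <- stats::aggregate(delta_current_pA ~ voltage_mV, data = ev,
                          FUN = length)
  agg$n <- cnt$delta_current_pA
  names(agg) <- c("voltage_mV", "mean_delta_pA", "n")
  n <- nrow(ev)
  n_volt <- nrow(agg)
  fallback <- n_volt < 2
  slope <- if (fallback) {
    mean(ev$conductance_nS)
  } else {
    sum(agg$n * agg$voltage_mV * agg$mean_delta_pA) /
      sum(agg$n * agg$voltage_mV^2)
  }
  sem <- if (n >= 2) stats::sd(ev$conductance_nS) / sqrt(n) else NA_real_
  out <- list(state = state, conductance_nS = slope, sem_nS = sem, n = n,
              n_voltages = n_volt, per_voltage = agg, fallback = fallback,
              low_n = (n_volt < 2 && n < 15))
  if (free_intercept && n_volt >= 2) {
    fit <- stats::lm(mean_delta_pA ~ voltage_mV, data = agg, weights = agg$n)
    out$intercept_diagnostic <- stats::setNames(stats::coef(fit),
                                                c("intercept_pA", "slope_nS"))
  }
  structure(out, class = "ohm_fit")
}

#' @export
print.ohm_fit <- function(x, ...) {
  cat(sprintf("<ohm_fit> %s: %.3f +/- %.3f nS (n = %d, %d voltages%s)\n",
              x$state, x$conductance_nS, x$sem_nS, x$n, x$n_voltages,
              if (x$fallback) ", single-voltage fallback" else ""))
  invisible(x)
}

# fixed-width bins aligned to multiples of bin_width
.g_hist <- function(values, bin_width, fit_range = NULL) {
  lo <- if (is.null(fit_range)) floor(min(values) / bin_width) * bin_width
        else fit_range[1]
  hi <- if (is.null(fit_range)) ceiling(max(values) / bin_width) * bin_width
        else fit_range[2]
  if (hi <= lo) hi <- lo + bin_width
  brk <- seq(lo, hi + bin_width / 2, by = bin_width)
  idx <- findInterval(values, brk, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(brk) - 1]
  counts <- tabulate(idx, nbins = length(brk) - 1)
  data.frame(bin_left = brk[-length(brk)], bin_right = brk[-1],
             bin_mid = (brk[-length(brk)] + brk[-1]) / 2, count = counts)
}

#' Histogram of closed-state conductances
#'
#' @param events numeric vector of conductances (nS) or an event data.frame
#'   whose rows exclude S0/BASELINE states.
#' @param bin_width_nS bin width, default 0.05 nS.
#' @param fit_range_nS optional `c(lo, hi)` range for the bins.
#' @return data.frame of class `g_histogram` with `bin_left`, `bin_right`,
#'   `bin_mid`, `count`.
#' @export
closed_state_histogram <- function(events, bin_width_nS = 0.05,
                                   fit_range_nS = NULL) {
  values <- if (is.data.frame(events)) events$conductance_nS else events
  if (length(values) == 0) stop("no closed events to histogram")
  h <- .g_hist(values, bin_width_nS, fit_range_nS)
  class(h) <- c("g_histogram", "data.frame")
  attr(h, "bin_width_nS") <- bin_width_nS
  attr(h, "n") <- length(values)
  h
}

# deterministic peak-based starting values for a k-component fit
.mixture_starts <- function(x, y, values, k, bin_width) {
  sdv <- max(stats::sd(values), bin_width / 2)
  peak_idx <- which(diff(sign(diff(c(-Inf, y, -Inf)))) == -2 & y > 0)
  peak_idx <- peak_idx[order(-y[peak_idx])]
  # enforce minimal separation of 2 bins between retained peaks
  keep <- integer(0)
  for (i in peak_idx) {
    if (all(abs(i - keep) > 2)) keep <- c(keep, i)
    if (length(keep) == k) break
  }
  starts <- list()
  if (length(keep) == k) {
    starts[[length(starts) + 1]] <-
      list(m = x[keep], s = rep(sdv / k, k), A = y[keep])
  }
  qs <- stats::quantile(values, (seq_len(k)) / (k + 1), names = FALSE)
  A_q <- pmax(y[pmin(pmax(findInterval(qs, x), 1), length(x))], 1)
  starts[[length(starts) + 1]] <- list(m = qs, s = rep(sdv / k, k), A = A_q)
  starts
}

.gauss_sum <- function(x, m, s, A) {
  out <- 0
  for (i in seq_along(m)) out <- out + A[i] * exp(-0.5 * ((x - m[i]) / s[i])^2)
  out
}

#' Fit a sum of Gaussians to a conductance histogram
#'
#' Least-squares fit of a k-component Gaussian sum to the binned amplitude
#' histogram (Levenberg-Marquardt), initialized deterministically from the
#' histogram peaks with quantile-based fallbacks; for `k = 2` the
#' single-Gaussian solution (second amplitude zero) is included among the
#' candidates, so the two-component fit can never be worse than the
#' one-component fit. The fit is deterministic for a fixed sample and bin
#' width.
#'
#' @param values conductance sample, nS (at least 30 values).
#' @param k number of components, 1 or 2.
#' @param fit_range_nS optional `c(lo, hi)`; values outside are dropped and
#'   bins cover exactly this range.
#' @param bin_width_nS histogram bin width (default 0.05 nS).
#' @return object of class `mixture_fit`: `components` (data.frame
#'   `mean_nS`, `sd_nS`, `weight`, sorted by descending mean), `r_squared`,
#'   `bin_width_nS`, `fit_range_nS`, `n`, `histogram` (with fitted column),
#'   `k`, `degenerate`.
#' @export
fit_mixture <- function(values, k, fit_range_nS = NULL, bin_width_nS = 0.05) {
  if (!k %in% 1:2) stop("k must be 1 or 2")
  if (!is.null(fit_range_nS)) {
    values <- values[values >= fit_range_nS[1] & values <= fit_range_nS[2]]
  }
  n <- length(values)
  if (n < 30) stop("need at least 30 values for a mixture fit (got ", n, ")")
  h <- .g_hist(values, bin_width_nS, fit_range_nS)
  x <- h$bin_mid
  y <- h$count
  if (sum(y > 0) < 2 || stats::sd(values) < 1e-12) {
    warning("degenerate sample (single occupied bin); reporting one component")
    comp <- data.frame(mean_nS = mean(values),
                       sd_nS = max(stats::sd(values), bin_width_nS / 4),
                       weight = 1)
    h$fitted <- NA_real_
    return(structure(list(components = comp, r_squared = NA_real_,
                          bin_width_nS = bin_width_nS,
                          fit_range_nS = fit_range_nS, n = n, histogram = h,
                          k = 1L, degenerate = TRUE),
                     class = "mixture_fit"))
  }
  sse_of <- function(m, s, A) sum((y - .gauss_sum(x, m, s, A))^2)
  lower_s <- bin_width_nS / 4
  fit_one <- function(start) {
    par_names <- c(paste0("m", seq_len(k)), paste0("s", seq_len(k)),
                   paste0("A", seq_len(k)))
    st <- stats::setNames(c(start$m, start$s, start$A), par_names)
    lo <- stats::setNames(c(rep(min(x) - bin_width_nS, k),
                            rep(lower_s, k), rep(0, k)), par_names)
    hi <- stats::setNames(c(rep(max(x) + bin_width_nS, k),
                            rep(diff(range(x)) + bin_width_nS, k),
                            rep(Inf, k)), par_names)
    form <- if (k == 1) {
      y ~ A1 * exp(-0.5 * ((x - m1) / s1)^2)
    } else {
      y ~ A1 * exp(-0.5 * ((x - m1) / s1)^2) +
        A2 * exp(-0.5 * ((x - m2) / s2)^2)
    }
    fit <- try(minpack.lm::nlsLM(
      form, data = data.frame(x = x, y = y), start = as.list(st),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    cf <- stats::coef(fit)
    list(m = cf[paste0("m", seq_len(k))], s = cf[paste0("s", seq_len(k))],
         A = cf[paste0("A", seq_len(k))],
         sse = sse_of(cf[paste0("m", seq_len(k))],
                      cf[paste0("s", seq_len(k))],
                      cf[paste0("A", seq_len(k))]))
  }
  starts <- .mixture_starts(x, y, values, k, bin_width_nS)
  candidates <- list()
  if (k == 2) {
    k1 <- fit_mixture(values, 1, fit_range_nS, bin_width_nS)
    m1 <- k1$components$mean_nS[1]
    s1 <- k1$components$sd_nS[1]
    A1 <- max(y)
    starts[[length(starts) + 1]] <-
      list(m = c(m1 - s1 / 2, m1 + s1 / 2), s = rep(max(s1 / 2, lower_s), 2),
           A = rep(A1, 2))
    # exact nested candidate: the k = 1 solution with a zero-weight twin
    if (!isTRUE(k1$degenerate)) {
      A1fit <- k1$fitted_amplitude %||% A1
      candidates[[length(candidates) + 1]] <-
        list(m = c(m1, m1 + s1), s = c(s1, s1), A = c(A1fit, 0),
             sse = sse_of(c(m1, m1 + s1), c(s1, s1), c(A1fit, 0)))
    }
  }
  for (st in starts) {
    f <- fit_one(st)
    if (!is.null(f)) candidates[[length(candidates) + 1]] <- f
  }
  if (length(candidates) == 0)
    stop("mixture fit failed to converge from all starting values")
  best <- candidates[[which.min(vapply(candidates, `[[`, 0, "sse"))]]
  ord <- order(-best$m)
  area <- best$A[ord] * best$s[ord]
  weight <- if (sum(area) > 0) area / sum(area) else rep(1 / k, k)
  comp <- data.frame(mean_nS = unname(best$m[ord]),
                     sd_nS = unname(best$s[ord]), weight = unname(weight))
  h$fitted <- .gauss_sum(x, best$m, best$s, best$A)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best$sse / sst)) else NA_real_
  structure(list(components = comp, r_squared = r2,
                 bin_width_nS = bin_width_nS, fit_range_nS = fit_range_nS,
                 n = n, histogram = h, k = as.integer(k), degenerate = FALSE,
                 fitted_amplitude = unname(best$A[ord][1])),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, n = %d, R^2 = %s\n", x$k, x$n,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  print(x$components, digits = 4)
  invisible(x)
}

#' Two-stage decomposition of closed-state conductances
#'
#' Stage 1 fits a sum of two Gaussians to all closed conductances, splitting
#' them into an upper (S1) and a lower (S2) population. Stage 2 restricts to
#' the S2 window (default 0.80-2.20 nS) and fits a second two-Gaussian sum,
#' resolving the S2A (upper) and S2B (lower) sub-states. Events are assigned
#' to the nearest component mean in sd units; both stage R-squared values,
#' the closed-state sample mean, and the single-Gaussian fitted mean are
#' reported.
#'
#' @param events conductance vector (nS) or event data.frame of closed
#'   events (no S0/BASELINE rows).
#' @param s2_window_nS window for stage 2, default `c(0.80, 2.20)` nS.
#' @param bin_width_nS histogram bin width.
#' @return object of class `closed_state_decomposition`: `components`
#'   (data.frame `state`, `mean_nS`, `sd_nS`, `weight`, `n_assigned`),
#'   `r_squared` (stage1/stage2), `stage1`, `stage2` (`mixture_fit`s),
#'   `single_gaussian`, `sample_mean_nS`, `assignment`, count and area
#'   ratios of S2A:S2B, `n`.
#' @export
decompose_closed_states <- function(events, s2_window_nS = c(0.80, 2.20),
                                    bin_width_nS = 0.05) {
  values <- if (is.data.frame(events)) events$conductance_nS else events
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no closed events supplied")
  if (length(values) < 100)
    warning("fewer than 100 closed events; decomposition may be unstable")
  stage1 <- fit_mixture(values, 2, bin_width_nS = bin_width_nS)
  if (isTRUE(stage1$degenerate)) {
    comp <- data.frame(state = "S1", mean_nS = stage1$components$mean_nS,
                       sd_nS = stage1$components$sd_nS, weight = 1,
                       n_assigned = length(values))
    return(structure(list(components = comp,
                          r_squared = c(stage1 = NA_real_, stage2 = NA_real_),
                          stage1 = stage1, stage2 = NULL,
                          single_gaussian = NULL,
                          sample_mean_nS = mean(values),
                          assignment = rep("S1", length(values)),
                          n = length(values)),
                     class = "closed_state_decomposition"))
  }
  s1_comp <- stage1$components[1, ]  # upper mean
  s2_comp <- stage1$components[2, ]
  in_window <- values >= s2_window_nS[1] & values <= s2_window_nS[2]
  stage2 <- NULL
  if (sum(in_window) >= 30) {
    stage2 <- fit_mixture(values[in_window], 2, fit_range_nS = s2_window_nS,
                          bin_width_nS = bin_width_nS)
    if (isTRUE(stage2$degenerate)) stage2 <- NULL
  } else {
    warning("S2 window contains fewer than 30 events; stage 2 skipped")
  }
  if (!is.null(stage2)) {
    comp <- data.frame(
      state = c("S1", "S2A", "S2B"),
      mean_nS = c(s1_comp$mean_nS, stage2$components$mean_nS),
      sd_nS = c(s1_comp$sd_nS, stage2$components$sd_nS),
      weight = c(s1_comp$weight, NA, NA)
    )
    # stage-2 weights are relative within the S2 window
    comp$weight[2:3] <- (1 - s1_comp$weight) * stage2$components$weight
  } else {
    comp <- data.frame(state = c("S1", "S2"),
                       mean_nS = c(s1_comp$mean_nS, s2_comp$mean_nS),
                       sd_nS = c(s1_comp$sd_nS, s2_comp$sd_nS),
                       weight = c(s1_comp$weight, s2_comp$weight))
  }
  z <- vapply(seq_len(nrow(comp)), function(i) {
    abs(values - comp$mean_nS[i]) / max(comp$sd_nS[i], 1e-6)
  }, numeric(length(values)))
  assignment <- comp$state[max.col(-z, ties.method = "first")]
  comp$n_assigned <- vapply(comp$state,
                            function(s) sum(assignment == s), 0L)
  single <- fit_mixture(values, 1, bin_width_nS = bin_width_nS)
  out <- list(
    components = comp,
    r_squared = c(stage1 = stage1$r_squared,
                  stage2 = if (is.null(stage2)) NA_real_ else stage2$r_squared),
    stage1 = stage1, stage2 = stage2, single_gaussian = single,
    sample_mean_nS = mean(values), assignment = assignment,
    values = values, n = length(values)
  )
  if (!is.null(stage2)) {
    nA <- comp$n_assigned[comp$state == "S2A"]
    nB <- comp$n_assigned[comp$state == "S2B"]
    out$s2a_s2b_count_ratio <- if (nB > 0) nA / nB else NA_real_
    wA <- stage2$components$weight[1]
    wB <- stage2$components$weight[2]
    out$s2a_s2b_area_ratio <- if (wB > 0) wA / wB else NA_real_
  }
  structure(out, class = "closed_state_decomposition")
}

#' @export
print.closed_state_decomposition <- function(x, ...) {
  cat("<closed_state_decomposition> n =", x$n, "closed events\n")
  print(x$components, digits = 4)
  cat(sprintf("  R^2: stage 1 = %.3f, stage 2 = %s; sample mean %.3f nS\n",
              x$r_squared[["stage1"]],
              ifelse(is.na(x$r_squared[["stage2"]]), "NA",
                     sprintf("%.3f", x$r_squared[["stage2"]])),
              x$sample_mean_nS))
  invisible(x)
}

#' Conductance as an integer percentage of the open state
#'
#' @param g_state state conductance, nS.
#' @param g_open open-state (S0) conductance, nS; must be positive.
#' @return integer percentage, rounded half-up.
#' @export
#' @examples
#' percent_of_open(2.61, 3.94)  # 66
#' percent_of_open(1.90, 3.94)  # 48
percent_of_open <- function(g_state, g_open) {
  if (any(g_open <= 0)) stop("g_open must be positive")
  as.integer(round_half_up(100 * g_state / g_open))
}

#' Closure probability as an integer percentage
#'
#' Fraction of traces (or events) in which the channel reached a closed
#' state, as a rounded percentage.
#'
#' @param n_closed number of traces showing closure.
#' @param n_total total number of traces; must be positive.
#' @return integer percentage, rounded half-up.
#' @export
#' @examples
#' closure_probability(30, 358)  # 8
closure_probability <- function(n_closed, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_closed < 0 || n_closed > n_total)
    stop("n_closed must lie in [0, n_total]")
  as.integer(round_half_up(100 * n_closed / n_total))
}
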