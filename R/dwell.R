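# Dwell-time statistics and polarity-asymmetry detection.
#
# A sojourn is a maximal run of consecutive same-state segments within one
# constant-voltage region. The first and last sojourn of each region are
# censored (their true lengths are unknown) and excluded from all dwell
# statistics.

.as_ideal_list <- function(idealizations) {
  if (inherits(idealizations, "idealization")) return(list(idealizations))
  if (is.data.frame(idealizations))
    return(list(list(segments = idealizations)))
  idealizations
}

# Merge consecutive same-state segments within each region into sojourns.
# Two adjacent same-label segments are merged only when their conductances
# agree within merge_tol_nS (healing spurious splits without collapsing
# genuine state-to-state switches that happen to share a label).
.sojourns <- function(idealizations, merge_tol_nS = 0.05,
                      relabel = function(seg) seg$state) {
  ideals <- .as_ideal_list(idealizations)
  out <- list()
  trace_id <- 0
  for (ideal in ideals) {
    trace_id <- trace_id + 1
    seg <- ideal$segments
    if (is.null(seg) || nrow(seg) == 0) next
    seg$label <- relabel(seg)
    for (reg in unique(seg$region)) {
      s <- seg[seg$region == reg, , drop = FALSE]
      if (nrow(s) == 0) next
      new_run <- c(TRUE, s$label[-1] != s$label[-nrow(s)] |
                     abs(s$conductance_nS[-1] -
                           s$conductance_nS[-nrow(s)]) > merge_tol_nS)
      run <- factor(cumsum(new_run), levels = unique(cumsum(new_run)))
      d <- data.frame(
        trace = trace_id, region = reg,
        state = as.vector(tapply(s$label, run, `[`, 1)),
        start_s = as.vector(tapply(s$start_s, run, min)),
        end_s = as.vector(tapply(s$end_s, run, max)),
        conductance_nS =
          as.vector(tapply(s$conductance_nS * s$duration_s, run, sum)) /
          as.vector(tapply(s$duration_s, run, sum))
      )
      d$duration_s <- d$end_s - d$start_s
      d$censored <- seq_len(nrow(d)) %in% c(1, nrow(d))
      out[[length(out) + 1]] <- d
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.state_stats <- function(durations) {
  n <- length(durations)
  list(mean_s = mean(durations),
       sem_s = if (n >= 2) stats::sd(durations) / sqrt(n) else NA_real_,
       n = n)
}

#' Dwell-time summary
#'
#' Per-state and overall dwell statistics from classified idealizations.
#' Sojourns are maximal same-state runs within a constant-voltage region;
#' the first and last sojourn of each region are censored and excluded, as
#' are baseline stretches. The overall statistic is the mean time spent in
#' any state before switching to the next. An `S2` union row aggregates
#' S2A, S2B and intermediate sojourns whose conductance falls inside the S2
#' window.
#'
#' @param idealizations one `idealization` or a list of them (or a bare
#'   event data.frame).
#' @param s2_window_nS conductance window defining the S2 union, nS.
#' @param merge_tol_nS maximal conductance difference for merging adjacent
#'   same-label segments into one sojourn.
#' @return object of class `dwell_summary`: `per_state` (data.frame `state`,
#'   `mean_s`, `sem_s`, `n`), `overall` (list), `s2_union` (list), and the
#'   underlying `sojourns` data.frame.
#' @export
dwell_summary <- function(idealizations, s2_window_nS = c(0.80, 2.20),
                          merge_tol_nS = 0.05) {
  soj <- .sojourns(idealizations, merge_tol_nS)
  if (is.null(soj)) stop("no segments supplied")
  keep <- soj[!soj$censored & soj$state != "BASELINE", , drop = FALSE]
  if (nrow(keep) == 0) stop("no uncensored sojourns available")
  per_state <- do.call(rbind, lapply(split(keep$duration_s, keep$state),
                                     function(d) as.data.frame(.state_stats(d))))
  per_state <- data.frame(state = rownames(per_state), per_state,
                          row.names = NULL)
  per_state <- per_state[order(match(per_state$state,
                                     c("S0", "S1", "S2A", "S2B",
                                       "INTERMEDIATE"))), ]
  rownames(per_state) <- NULL
  overall <- .state_stats(keep$duration_s)

  # S2 union: relabel, re-merge, re-censor
  relabel_s2 <- function(seg) {
    lab <- seg$state
    lab[lab %in% c("S2A", "S2B")] <- "S2"
    inter <- lab == "INTERMEDIATE" &
      seg$conductance_nS >= s2_window_nS[1] &
      seg$conductance_nS <= s2_window_nS[2]
    lab[inter] <- "S2"
    lab
  }
  soj2 <- .sojourns(idealizations, merge_tol_nS = Inf, relabel = relabel_s2)
  s2 <- soj2[!soj2$censored & soj2$state == "S2", , drop = FALSE]
  s2_union <- if (nrow(s2) > 0) .state_stats(s2$duration_s) else
    list(mean_s = NA_real_, sem_s = NA_real_, n = 0L)

  structure(list(per_state = per_state, overall = overall,
                 s2_union = s2_union, sojourns = keep,
                 s2_window_nS = s2_window_nS),
            class = "dwell_summary")
}

#' @export
print.dwell_summary <- function(x, ...) {
  cat("<dwell_summary>\n")
  print(x$per_state, digits = 4)
  cat(sprintf("  overall: %.3f +/- %.3f s (n = %d)\n",
              x$overall$mean_s, x$overall$sem_s, x$overall$n))
  if (x$s2_union$n > 0)
    cat(sprintf("  S2 union: %.3f +/- %.3f s (n = %d)\n",
                x$s2_union$mean_s, x$s2_union$sem_s, x$s2_union$n))
  invisible(x)
}

#' Fold change between two dwell (or other) means
#'
#' @param a_mean_s numerator mean.
#' @param b_mean_s denominator mean; must be positive.
#' @param rounding `"none"`, `"integer"` (nearest integer), `"ten"` (nearest
#'   ten) or `"tenth"` (one decimal); half-up in every case.
#' @return the (optionally rounded) ratio.
#' @export
#' @examples
#' fold_change(1836.60, 10.34, "ten")     # 180
#' fold_change(36.70, 3.61, "integer")    # 10
#' fold_change(2.34, 1.70, "tenth")       # 1.4
fold_change <- function(a_mean_s, b_mean_s,
                        rounding = c("none", "integer", "ten", "tenth")) {
  rounding <- match.arg(rounding)
  if (b_mean_s <= 0) stop("denominator mean must be positive")
  ratio <- a_mean_s / b_mean_s
  switch(rounding,
         none = ratio,
         integer = round_half_up(ratio, 0),
         ten = round_half_up(ratio, -1),
         tenth = round_half_up(ratio, 1))
}

#' Detect polarity-asymmetric gating
#'
#' Computes the fraction of analyzable time spent in closed (non-S0,
#' non-baseline) states separately under positive and negative voltage.
#' Gating is called asymmetric when one polarity shows essentially no
#' closure (fraction below `closed_tol`) while the other closes for more
#' than `closed_floor` of the time; the inferred orientation is the polarity
#' sign that shows closure.
#'
#' @param idealizations classified idealization(s) containing both voltage
#'   polarities.
#' @param closed_tol closed-time fraction below which a polarity counts as
#'   "never closing" (default 0.005).
#' @param closed_floor closed-time fraction above which a polarity counts as
#'   "closing" (default 0.02).
#' @return object of class `asymmetry_report`: `closed_fraction_pos`,
#'   `closed_fraction_neg`, `asymmetric`, `inferred_orientation` (+1, -1 or
#'   `NA`), `analyzable_s_pos`, `analyzable_s_neg`.
#' @export
detect_asymmetry <- function(idealizations, closed_tol = 0.005,
                             closed_floor = 0.02) {
  ideals <- .as_ideal_list(idealizations)
  seg <- do.call(rbind, lapply(ideals, function(i) i$segments))
  seg <- seg[!is.na(seg$state) & seg$state != "BASELINE", , drop = FALSE]
  pos <- seg$voltage_mV > 0
  neg <- seg$voltage_mV < 0
  if (!any(pos) || !any(neg))
    stop("asymmetry detection needs recordings at both voltage polarities; ",
         "record both signs and re-run")
  frac <- function(idx) {
    tot <- sum(seg$duration_s[idx])
    closed <- sum(seg$duration_s[idx & seg$state != "S0"])
    closed / tot
  }
  fp <- frac(pos)
  fn <- frac(neg)
  asym <- (fp <= closed_tol && fn > closed_floor) ||
    (fn <= closed_tol && fp > closed_floor)
  orientation <- if (!asym) NA_integer_ else if (fp > fn) 1L else -1L
  structure(list(closed_fraction_pos = fp, closed_fraction_neg = fn,
                 asymmetric = asym, inferred_orientation = orientation,
                 analyzable_s_pos = sum(seg$duration_s[pos]),
                 analyzable_s_neg = sum(seg$duration_s[neg])),
            class = "asymmetry_report")
}

#' @export
print.asymmetry_report <- function(x, ...) {
  cat(sprintf("<asymmetry_report> closed fraction: %.4f (V>0), %.4f (V<0)\n",
              x$closed_fraction_pos, x$closed_fraction_neg))
  cat("  asymmetric:", x$asymmetric,
      if (x$asymmetric) paste0("(orientation ", x$inferred_orientation, ")"),
      "\n")
  invisible(x)
}
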