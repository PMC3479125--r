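# Trace idealization: baseline estimation, change-point segmentation of the
# current record into piecewise-constant events, and classification of event
# conductances against a preset's reference states.
#
# Levels are defined relative to a clear zero-channel baseline; each event's
# conductance is (mean current - baseline) / voltage, which is positive at
# both polarities for a conducting channel.

#' Estimate the zero-channel baseline current
#'
#' Finds the lowest-conductance cluster of the per-sample I/V histogram and
#' returns its mean current in pA. For a record that starts before channel
#' insertion this is the (possibly offset) zero-channel level. If the lowest
#' cluster sits above `max_baseline_nS` the trace contains no baseline-level
#' samples and the value is returned with a warning. A trace with only zero
#' voltage has no conductance axis; the median current is returned with a
#' warning and attribute `flagged = TRUE`.
#'
#' @param trace a `current_trace`, preferably at the analysis rate.
#' @param bin_width_nS histogram bin width on the conductance axis.
#' @param max_baseline_nS largest |conductance| still considered baseline.
#' @return baseline in pA (attribute `flagged` when the fallback was used).
#' @export
estimate_baseline <- function(trace, bin_width_nS = 0.05,
                              max_baseline_nS = 0.5) {
  if (length(trace$current_pA) < trace$fs_Hz)
    stop("need at least 1 s of data to estimate a baseline")
  nz <- trace$voltage_mV != 0
  if (!any(nz)) {
    warning("all-zero-voltage trace: baseline undefined in conductance terms; ",
            "falling back to the median current")
    return(structure(stats::median(trace$current_pA), flagged = TRUE))
  }
  g <- abs(trace$current_pA[nz]) / abs(trace$voltage_mV[nz])
  brk <- seq(0, max(g) + bin_width_nS, by = bin_width_nS)
  counts <- tabulate(findInterval(g, brk, rightmost.closed = TRUE),
                     nbins = length(brk) - 1)
  occupied <- counts >= max(2, 1e-5 * length(g))
  if (!any(occupied)) occupied <- counts > 0
  # lowest cluster: first maximal run of occupied bins
  first <- which(occupied)[1]
  last <- first
  while (last + 1 <= length(occupied) && occupied[last + 1]) last <- last + 1
  in_cluster <- g >= brk[first] & g < brk[last + 1]
  mode_bin <- first + which.max(counts[first:last]) - 1
  mode_g <- (brk[mode_bin] + brk[mode_bin + 1]) / 2
  if (mode_g > max_baseline_nS) {
    warning("no baseline-level samples found; using the lowest-conductance ",
            "cluster (~", round(mode_g, 2), " nS) as baseline")
  }
  mean(trace$current_pA[nz][in_cluster])
}

# Recursive binary change-point splitting on the mean (CUSUM). Returns split
# indices k such that samples 1..k and (k+1).. belong to different runs.
.split_points <- function(x, threshold, min_len) {
  n <- length(x)
  if (n < 2 * min_len) return(integer(0))
  cs <- cumsum(x - mean(x))
  ks <- min_len:(n - min_len)
  k <- ks[which.max(abs(cs[ks]))]
  if (abs(mean(x[1:k]) - mean(x[(k + 1):n])) > threshold) {
    c(.split_points(x[1:k], threshold, min_len), k,
      k + .split_points(x[(k + 1):n], threshold, min_len))
  } else {
    integer(0)
  }
}

# Merge short transition artifacts: a brief run whose mean lies strictly
# between its two neighbors' means is a step-blend left by decimation at a
# level change, not a state visit (a genuine brief sojourn lies outside the
# band spanned by its flanking levels). Merged into the closer neighbor.
.merge_transition_artifacts <- function(bounds, x, min_len) {
  repeat {
    if (length(bounds) < 3) return(bounds)
    starts <- c(1L, utils::head(bounds, -1) + 1L)
    lens <- bounds - starts + 1L
    means <- mapply(function(a, b) mean(x[a:b]), starts, bounds)
    k <- length(bounds)
    mid <- 2:(k - 1)
    between <- (means[mid] - means[mid - 1]) *
      (means[mid] - means[mid + 1]) < 0
    cand <- mid[between & lens[mid] < 2L * min_len]
    if (length(cand) == 0) return(bounds)
    i <- cand[which.min(lens[cand])]
    j <- if (abs(means[i] - means[i - 1]) <= abs(means[i] - means[i + 1]))
      i - 1 else i + 1
    bounds <- bounds[-min(i, j)]
  }
}

# Merge runs shorter than min_len into the neighbor with the closer mean.
.merge_short_runs <- function(bounds, x, min_len) {
  # bounds: integer vector of run end indices (last == length(x))
  repeat {
    starts <- c(1L, utils::head(bounds, -1) + 1L)
    lens <- bounds - starts + 1L
    if (length(bounds) == 1 || all(lens >= min_len)) break
    i <- which.min(ifelse(lens < min_len, lens, Inf))
    means <- mapply(function(a, b) mean(x[a:b]), starts, bounds)
    if (i == 1) {
      j <- 2
    } else if (i == length(bounds)) {
      j <- i - 1
    } else {
      j <- if (abs(means[i] - means[i - 1]) <= abs(means[i] - means[i + 1]))
        i - 1 else i + 1
    }
    bounds <- bounds[-min(i, j)]
  }
  bounds
}

#' Segment a current trace into piecewise-constant events
#'
#' Each constant-voltage region is partitioned by recursive binary
#' change-point splitting on the running mean; a split is accepted when the
#' two sides' mean currents differ by more than `jump_threshold_pA` (default:
#' 4 times a robust noise-sd estimate from first differences). Runs shorter
#' than `min_duration_s` are merged into the neighbor with the closer mean.
#' Zero-voltage regions are not analyzable and carry no segments.
#'
#' @param trace a `current_trace` decimated to the analysis rate
#'   (typically 200 Hz).
#' @param params list of segmentation parameters: `min_duration_s` (default
#'   0.025 s), `jump_threshold_pA` (default `NULL` = 4 x noise sd estimate),
#'   `jump_sd_mult` (default 4), `edge_trim_s` (samples discarded at each
#'   voltage-step edge, default 0).
#' @param baseline_pA zero-channel current; estimated with
#'   [estimate_baseline()] when `NULL`.
#' @return object of class `idealization`: list with `segments` (data.frame:
#'   `start_s`, `end_s`, `duration_s`, `voltage_mV`, `mean_current_pA`,
#'   `delta_current_pA`, `conductance_nS`, `n_samples`, `region`, `state`),
#'   `baseline_pA`, `params`, `fs_Hz`.
#' @export
segment_trace <- function(trace, params = list(), baseline_pA = NULL) {
  if (length(trace$current_pA) == 0) stop("empty trace")
  p <- utils::modifyList(
    list(min_duration_s = 0.025, jump_threshold_pA = NULL,
         jump_sd_mult = 4, edge_trim_s = 0),
    params
  )
  fs <- trace$fs_Hz
  if (is.null(baseline_pA)) baseline_pA <- estimate_baseline(trace)
  min_len <- max(2L, as.integer(round(p$min_duration_s * fs)))
  r <- rle(trace$voltage_mV)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == 0) next
    i0 <- starts[i]; i1 <- ends[i]
    trim <- as.integer(round(p$edge_trim_s * fs))
    i0 <- i0 + trim; i1 <- i1 - trim
    if (i1 - i0 + 1 < min_len) next
    x <- trace$current_pA[i0:i1]
    thr <- p$jump_threshold_pA
    if (is.null(thr)) {
      sd_est <- 1.4826 * stats::median(abs(diff(x))) / sqrt(2)
      thr <- p$jump_sd_mult * sd_est
    }
    bounds <- sort(unique(c(.split_points(x, thr, 2L), length(x))))
    bounds <- .merge_short_runs(bounds, x, min_len)
    bounds <- .merge_transition_artifacts(bounds, x, min_len)
    run_starts <- c(1L, utils::head(bounds, -1) + 1L)
    mu <- mapply(function(a, b) mean(x[a:b]), run_starts, bounds)
    segs[[length(segs) + 1]] <- data.frame(
      start_s = (i0 - 1 + run_starts - 1) / fs,
      end_s = (i0 - 1 + bounds) / fs,
      voltage_mV = v,
      mean_current_pA = mu,
      n_samples = bounds - run_starts + 1L,
      region = i
    )
  }
  if (length(segs) == 0) stop("no analyzable (non-zero voltage) regions")
  segments <- do.call(rbind, segs)
  segments$duration_s <- segments$end_s - segments$start_s
  segments$delta_current_pA <- segments$mean_current_pA - baseline_pA
  segments$conductance_nS <- segments$delta_current_pA / segments$voltage_mV
  segments$state <- NA_character_
  segments <- segments[, c("start_s", "end_s", "duration_s", "voltage_mV",
                           "mean_current_pA", "delta_current_pA",
                           "conductance_nS", "n_samples", "region", "state")]
  rownames(segments) <- NULL
  structure(list(segments = segments, baseline_pA = baseline_pA,
                 params = p, fs_Hz = fs),
            class = "idealization")
}

#' Classify a conductance against reference states
#'
#' A conductance g is assigned to the reference state r with
#' `|g - r| <= window * r`; when several states qualify, the one with the
#' smallest relative distance `|g - r| / r` wins. A value matching no state
#' is `INTERMEDIATE`, unless it lies below the smallest reference's lower
#' window edge by more than one further window width, in which case it is
#' `BASELINE`.
#'
#' @param conductance_nS conductance value(s), nS.
#' @param refs named numeric vector of reference conductances, e.g.
#'   `build_preset("native")$states`.
#' @param window half-width of the acceptance window as a fraction of each
#'   reference (default 0.05, i.e. +/-5 percent).
#' @return character vector of state labels.
#' @export
#' @examples
#' refs <- build_preset("native")$states
#' classify_state(3.94, refs)            # "S0"
#' classify_state(2.30, refs[c("S1", "S2A")])  # "INTERMEDIATE"
classify_state <- function(conductance_nS, refs, window = 0.05) {
  if (window <= 0 || window >= 0.5) stop("window must lie in (0, 0.5)")
  if (any(refs <= 0)) stop("reference conductances must be positive")
  tol <- 1e-9
  vapply(conductance_nS, function(g) {
    d <- abs(g - refs)
    ok <- d <= window * refs * (1 + tol)
    if (any(ok)) {
      rel <- d / refs
      names(refs)[ok][which.min(rel[ok])]
    } else if (g < min(refs) * (1 - 2 * window) * (1 - tol)) {
      "BASELINE"
    } else {
      "INTERMEDIATE"
    }
  }, character(1))
}

#' Classify all segments of an idealization
#'
#' @param ideal an `idealization` from [segment_trace()].
#' @param refs named reference conductances (nS).
#' @param window classification window (fraction), see [classify_state()].
#' @return the `idealization` with the `state` column filled in.
#' @export
classify_segments <- function(ideal, refs, window = 0.05) {
  ideal$segments$state <- classify_state(ideal$segments$conductance_nS,
                                         refs, window)
  ideal$params$window <- window
  ideal$params$refs <- refs
  ideal
}

#' Idealize a trace in one call
#'
#' Convenience wrapper: [estimate_baseline()], [segment_trace()] and, when
#' `refs` is given, [classify_segments()].
#'
#' @inheritParams segment_trace
#' @inheritParams classify_segments
#' @return a classified `idealization`.
#' @export
idealize_trace <- function(trace, refs = NULL, window = 0.05,
                           params = list(), baseline_pA = NULL) {
  ideal <- segment_trace(trace, params = params, baseline_pA = baseline_pA)
  if (!is.null(refs)) ideal <- classify_segments(ideal, refs, window)
  ideal
}

#' @export
print.idealization <- function(x, ...) {
  cat("<idealization>", nrow(x$segments), "segments, baseline",
      round(x$baseline_pA, 3), "pA\n")
  if (!all(is.na(x$segments$state))) {
    print(table(x$segments$state))
  }
  invisible(x)
}

#' Write an event table to CSV
#' @param ideal an `idealization`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ideal, path) {
  cols <- c("start_s", "end_s", "duration_s", "voltage_mV",
            "mean_current_pA", "conductance_nS", "state")
  utils::write.csv(ideal$segments[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path CSV path.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("start_s", "end_s", "duration_s", "voltage_mV",
            "mean_current_pA", "conductance_nS", "state")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("event table is missing columns: ", paste(missing, collapse = ", "))
  if (!"delta_current_pA" %in% names(df))
    df$delta_current_pA <- df$conductance_nS * df$voltage_mV
  if (!"region" %in% names(df)) {
    brk <- c(TRUE, abs(df$start_s[-1] - df$end_s[-nrow(df)]) > 1e-9 |
               df$voltage_mV[-1] != df$voltage_mV[-nrow(df)])
    df$region <- cumsum(brk)
  }
  df
}
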