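# Trace file format, run configuration, and the end-to-end pipeline.
#
# Canonical trace format: plain CSV with '#'-prefixed key=value header lines
# (fs_hz required; preset, seed, noise_sd_pa, n_channels optional) followed
# by a header row and three numeric columns time_s, current_pA, voltage_mV
# in any order. Values are serialized with full precision so that
# write -> read round-trips bit-exactly.

#' Write a current trace to CSV
#'
#' @param trace a `current_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- trace$meta
  meta$fs_hz <- trace$fs_Hz
  keys <- unique(c("fs_hz", names(meta)))
  hdr <- vapply(keys, function(k) {
    v <- meta[[k]]
    if (is.null(v) || length(v) != 1) return(NA_character_)
    vs <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    paste0("# ", tolower(k), "=", vs)
  }, character(1))
  hdr <- hdr[!is.na(hdr)]
  tm <- trace_times(trace)
  body <- sprintf("%.17g,%.17g,%.17g", tm, trace$current_pA, trace$voltage_mV)
  writeLines(c(hdr, "time_s,current_pA,voltage_mV", body), path)
  invisible(path)
}

#' Read a current trace from CSV
#'
#' @param path file written by [write_trace()] (or any conforming CSV).
#' @return a `current_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, n = 200)
  hdr_lines <- grep("^#", lines)
  if (length(hdr_lines) > 0 && !identical(hdr_lines, seq_along(hdr_lines)))
    stop("header ('#') lines must precede the data block")
  meta <- list()
  for (i in hdr_lines) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0)
      stop("malformed header at line ", i, ": expected key=value, got '",
           lines[i], "'")
    key <- trimws(substr(kv, 1, eq - 1))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  if (is.null(meta$fs_hz))
    stop("trace header is missing the required key 'fs_hz'")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "current_pA", "voltage_mV")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("trace file must have columns time_s, current_pA, voltage_mV; ",
         "missing: ", paste(missing_cols, collapse = ", "))
  n_hdr <- length(hdr_lines) + 1  # '#' lines plus the column-name row
  for (col in need) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric value in column '", col, "' at line ",
           n_hdr + bad, " of ", path)
    }
  }
  for (col in need) df[[col]] <- as.numeric(df[[col]])
  fs <- meta$fs_hz
  dt <- diff(df$time_s)
  if (length(dt) > 0 &&
      any(abs(dt - 1 / fs) > 1e-6 / fs))
    stop("time column is not uniformly spaced at 1/fs_hz = ",
         signif(1 / fs, 6), " s")
  meta$fs_hz <- NULL
  names(meta) <- sub("^noise_sd_pa$", "noise_sd_pA", names(meta))
  .current_trace(fs, df$current_pA, df$voltage_mV, meta)
}

# ---------------------------------------------------------------------------
# Run configuration

.config_schema <- function() {
  list(
    preset = NA, protocol = NA, trace_file = NA, seed = NA,
    fs_hz = NA, analysis_fs_hz = NA, n_channels = NA, baseline_lead_s = NA,
    out_dir = NA,
    idealization = list(window = NA, min_duration_s = NA,
                        jump_threshold_pA = NA, jump_sd_mult = NA,
                        edge_trim_s = NA),
    analysis = list(bin_width_nS = NA, s2_window_nS = NA,
                    dwell_merge_tol_nS = NA, closed_tol = NA,
                    closed_floor = NA)
  )
}

.validate_config <- function(config) {
  schema <- .config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(names(schema), collapse = ", "))
  for (grp in c("idealization", "analysis")) {
    if (!is.null(config[[grp]])) {
      bad <- setdiff(names(config[[grp]]), names(schema[[grp]]))
      if (length(bad) > 0)
        stop("unknown key(s) in '", grp, "': ", paste(bad, collapse = ", "))
    }
  }
  invisible(config)
}

#' Read a pipeline run configuration from JSON
#'
#' The configuration is validated against the published schema; unknown keys
#' are rejected. See [run_pipeline()] for the recognized fields.
#'
#' @param path JSON file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  .validate_config(config)
  config
}

# ---------------------------------------------------------------------------
# Pipeline

#' Run the full gating-analysis pipeline
#'
#' Composes the module operations in recording order: simulate (or ingest) a
#' current trace, decimate to the analysis rate, estimate the baseline,
#' segment into events, classify against the preset's reference states, fit
#' per-state Ohm conductances, decompose the closed-state amplitude
#' histogram into sub-states, and compute dwell-time statistics and (when
#' both polarities were recorded) the asymmetry report. Deterministic for a
#' fixed configuration and seed.
#'
#' Configuration fields: `preset` (name or inline preset list), `protocol`
#' (steps or file path), `trace_file` (skip simulation and read a trace),
#' `seed`, `fs_hz` (default 5000), `analysis_fs_hz` (default 200),
#' `n_channels` (default 1), `baseline_lead_s` (default 2), `out_dir`, and
#' nested `idealization` / `analysis` parameter lists.
#'
#' @param config configuration list or path to a JSON config file.
#' @param out_dir output directory (overrides `config[["out_dir"]]`); created if
#'   needed. When `NULL` and the config has no `out_dir`, nothing is written.
#' @return (invisibly) a list with `trace`, `idealization`, `ohm_fits`,
#'   `decomposition`, `dwell`, `asymmetry`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  .validate_config(config)
  if (is.null(config[["preset"]])) stop("config must name a preset")
  preset <- as_channel_preset(config[["preset"]])  # fails fast on unknown preset
  seed <- config[["seed"]] %||% 1L
  fs <- config[["fs_hz"]] %||% 5000
  afs <- config[["analysis_fs_hz"]] %||% 200
  idp <- utils::modifyList(
    list(window = 0.05, min_duration_s = 0.025, jump_threshold_pA = NULL,
         jump_sd_mult = 4, edge_trim_s = 0),
    config[["idealization"]] %||% list()
  )
  anp <- utils::modifyList(
    list(bin_width_nS = 0.05, s2_window_nS = c(0.80, 2.20),
         dwell_merge_tol_nS = 0.05, closed_tol = 0.005, closed_floor = 0.02),
    config[["analysis"]] %||% list()
  )
  out_dir <- out_dir %||% config[["out_dir"]]

  if (!is.null(config[["trace_file"]])) {
    trace <- read_trace(config[["trace_file"]])
  } else {
    if (is.null(config[["protocol"]])) stop("config must give a protocol or a trace_file")
    protocol <- if (is.character(config[["protocol"]])) {
      read_protocol(config[["protocol"]])
    } else {
      as_voltage_protocol(config[["protocol"]])
    }
    trace <- simulate_trace(preset, protocol, fs_Hz = fs, seed = seed,
                            n_channels = config[["n_channels"]] %||% 1,
                            baseline_lead_s = config[["baseline_lead_s"]] %||% 2)
  }
  if (trace$fs_Hz > afs) trace <- decimate_trace(trace, afs)

  baseline <- estimate_baseline(trace, bin_width_nS = anp$bin_width_nS)
  ideal <- segment_trace(trace,
                         params = idp[c("min_duration_s", "jump_threshold_pA",
                                        "jump_sd_mult", "edge_trim_s")],
                         baseline_pA = as.numeric(baseline))
  ideal <- classify_segments(ideal, preset$states, window = idp$window)
  ev <- ideal$segments

  # Ohm fits for every preset state observed in the events
  ohm_fits <- list()
  for (s in names(preset$states)) {
    if (any(ev$state == s, na.rm = TRUE)) ohm_fits[[s]] <- ohm_fit(ev, s)
  }

  # closed-state sample: classified closed states plus intermediates below
  # the midpoint between the highest closed reference and S0
  closed_refs <- preset$states[setdiff(names(preset$states), "S0")]
  closed_cut <- if (length(closed_refs) > 0 && "S0" %in% names(preset$states))
    (max(closed_refs) + preset$states[["S0"]]) / 2 else Inf
  closed_idx <- ev$state %in% names(closed_refs) |
    (ev$state == "INTERMEDIATE" & ev$conductance_nS < closed_cut &
       ev$conductance_nS > 0)
  closed_g <- ev$conductance_nS[closed_idx]
  decomposition <- NULL
  if (length(closed_g) >= 30) {
    decomposition <- withCallingHandlers(
      decompose_closed_states(closed_g, s2_window_nS = anp$s2_window_nS,
                              bin_width_nS = anp$bin_width_nS),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  dwell <- tryCatch(
    dwell_summary(ideal, s2_window_nS = anp$s2_window_nS,
                  merge_tol_nS = anp$dwell_merge_tol_nS),
    error = function(e) NULL)
  asymmetry <- if (any(ev$voltage_mV > 0) && any(ev$voltage_mV < 0)) {
    detect_asymmetry(ideal, closed_tol = anp$closed_tol,
                     closed_floor = anp$closed_floor)
  } else NULL

  report <- .build_report(preset, baseline, ohm_fits, decomposition, dwell,
                          asymmetry, seed, idp, anp)
  bundle <- list(trace = trace, idealization = ideal, ohm_fits = ohm_fits,
                 decomposition = decomposition, dwell = dwell,
                 asymmetry = asymmetry, report = report)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, config)
  invisible(bundle)
}

.ohm_to_list <- function(f) {
  list(conductance_nS = f$conductance_nS, sem_nS = f$sem_nS, n = f$n,
       n_voltages = f$n_voltages, fallback = f$fallback)
}

.build_report <- function(preset, baseline, ohm_fits, decomposition, dwell,
                          asymmetry, seed, idp, anp) {
  rep_ <- list(
    preset = preset$name,
    seed = seed,
    baseline_pA = as.numeric(baseline),
    parameters = list(idealization = idp[!vapply(idp, is.null, TRUE)],
                      analysis = anp),
    ohm_fits = lapply(ohm_fits, .ohm_to_list)
  )
  if (!is.null(ohm_fits$S0)) {
    g0 <- ohm_fits$S0$conductance_nS
    rep_$percent_of_open <- lapply(
      ohm_fits[setdiff(names(ohm_fits), "S0")],
      function(f) percent_of_open(f$conductance_nS, g0))
  }
  if (!is.null(decomposition)) {
    rep_$closed_states <- list(
      components = decomposition$components,
      r_squared_stage1 = unname(decomposition$r_squared[["stage1"]]),
      r_squared_stage2 = unname(decomposition$r_squared[["stage2"]]),
      sample_mean_nS = decomposition$sample_mean_nS,
      single_gaussian_mean_nS =
        decomposition$single_gaussian$components$mean_nS[1],
      s2a_s2b_count_ratio = decomposition$s2a_s2b_count_ratio %||% NA_real_,
      s2a_s2b_area_ratio = decomposition$s2a_s2b_area_ratio %||% NA_real_,
      n = decomposition$n
    )
    # t-test validation of the sub-state separation, from assigned events
    grp <- split(decomposition$values, decomposition$assignment)
    pair_test <- function(a, b) {
      if (is.null(grp[[a]]) || is.null(grp[[b]]) ||
          length(grp[[a]]) < 2 || length(grp[[b]]) < 2) return(NULL)
      tt <- welch_t(summarize_sample(grp[[a]]), summarize_sample(grp[[b]]))
      list(t = tt$t_statistic, df = tt$degrees_of_freedom, p = tt$p_value)
    }
    comparisons <- list(
      S1_vs_S2 = if (!is.null(grp$S1)) {
        s2v <- c(grp$S2A, grp$S2B, grp$S2)
        if (length(grp$S1) >= 2 && length(s2v) >= 2) {
          tt <- welch_t(summarize_sample(grp$S1), summarize_sample(s2v))
          list(t = tt$t_statistic, df = tt$degrees_of_freedom,
               p = tt$p_value)
        }
      },
      S2A_vs_S2B = pair_test("S2A", "S2B")
    )
    rep_$comparisons <- comparisons[!vapply(comparisons, is.null, TRUE)]
  }
  if (!is.null(dwell)) {
    rep_$dwell <- list(per_state = dwell$per_state, overall = dwell$overall,
                       s2_union = dwell$s2_union)
  }
  if (!is.null(asymmetry)) {
    rep_$asymmetry <- unclass(asymmetry)
  }
  rep_
}

.write_bundle <- function(bundle, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_events(bundle$idealization, file.path(out_dir, "events.csv"))
  jsonlite::write_json(bundle$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  dj <- list(dwell = bundle$report$dwell, asymmetry = bundle$report$asymmetry)
  jsonlite::write_json(dj, file.path(out_dir, "dwell.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  if (!is.null(bundle$decomposition)) {
    h <- bundle$decomposition$stage1$histogram
    h$fitted_k2 <- h$fitted
    h$fitted <- NULL
    h$fitted_k1 <- bundle$decomposition$single_gaussian$histogram$fitted
    utils::write.csv(h, file.path(out_dir, "histogram.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  log_lines <- c(
    paste0("vdacgate ", as.character(utils::packageVersion("vdacgate"))),
    paste0("R ", R.version.string),
    paste0("timestamp ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed ", bundle$report$seed),
    paste0("config ", jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA, na = "null"))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
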