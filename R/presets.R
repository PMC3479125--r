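# Channel-variant gating presets.
#
# Conductances come from bilayer reconstitution measurements of murine VDAC1
# and its engineered variants (open state S0, closed states S1, S2A, S2B);
# mean dwell times from the corresponding dwell-time figures. Where a variant
# shows a single closed state it is carried under the S2A label. The closed
# state of the oxidized A14C-S193C variant is effectively absorbing (the
# channel fails to reopen), approximated by a very large mean dwell.

.preset_table <- function() {
  list(
    native = list(
      states = c(S0 = 3.94, S1 = 2.61, S2A = 2.03, S2B = 1.48),
      mean_dwell_s = c(S0 = 27.40, S1 = 2.92, S2A = 2.45, S2B = 2.45),
      transition_weights = list(
        S0 = c(S1 = 0.50, S2A = 0.35, S2B = 0.15),
        S1 = c(S0 = 1), S2A = c(S0 = 1), S2B = c(S0 = 1)
      ),
      asymmetric = FALSE, orientation = NA_integer_
    ),
    cysteinless = list(
      states = c(S0 = 3.78, S1 = 2.55, S2A = 1.78),
      mean_dwell_s = c(S0 = 36.70, S1 = 3.61, S2A = 3.10),
      transition_weights = list(
        S0 = c(S1 = 0.5, S2A = 0.5), S1 = c(S0 = 1), S2A = c(S0 = 1)
      ),
      asymmetric = FALSE, orientation = NA_integer_
    ),
    delta21 = list(
      # N-terminally truncated channel: constitutively open, one state.
      states = c(S0 = 4.00),
      mean_dwell_s = c(S0 = 27.40),
      transition_weights = list(S0 = numeric(0)),
      asymmetric = FALSE, orientation = NA_integer_
    ),
    `A14C-S193C_ox` = list(
      # Cross-link at the pore midpoint: S0-dominated, rare closure to an
      # S2-like state from which the channel does not reopen.
      states = c(S0 = 3.74, S2A = 1.85),
      mean_dwell_s = c(S0 = 1836.60, S2A = 1e6),
      transition_weights = list(S0 = c(S2A = 1), S2A = c(S0 = 1)),
      asymmetric = FALSE, orientation = NA_integer_
    ),
    `A14C-S193C_red` = list(
      states = c(S0 = 3.75, S1 = 2.55, S2A = 1.67),
      mean_dwell_s = c(S0 = 27.40, S1 = 2.92, S2A = 2.45),
      transition_weights = list(
        S0 = c(S1 = 0.5, S2A = 0.5), S1 = c(S0 = 1), S2A = c(S0 = 1)
      ),
      asymmetric = FALSE, orientation = NA_integer_
    ),
    `V3C-K119C_ox` = list(
      # Cross-link at the pore base: closure permitted under one voltage
      # polarity only, set by the channel's orientation in the bilayer.
      states = c(S0 = 3.76, S2A = 1.77),
      mean_dwell_s = c(S0 = 5.74, S2A = 2.55),
      transition_weights = list(S0 = c(S2A = 1), S2A = c(S0 = 1)),
      asymmetric = TRUE, orientation = 1L
    ),
    `V3C-K119C_red` = list(
      states = c(S0 = 3.98, S1 = 2.70, S2A = 2.05),
      mean_dwell_s = c(S0 = 27.40, S1 = 2.92, S2A = 2.45),
      transition_weights = list(
        S0 = c(S1 = 0.5, S2A = 0.5), S1 = c(S0 = 1), S2A = c(S0 = 1)
      ),
      asymmetric = FALSE, orientation = NA_integer_
    )
  )
}

#' Registered channel preset names
#'
#' @return character vector of preset names accepted by [build_preset()].
#' @export
list_presets <- function() names(.preset_table())

#' Construct a channel gating preset
#'
#' A preset bundles everything the semi-Markov gating simulator needs for one
#' channel variant: per-state conductances (nS), mean dwell times (s),
#' successor weights of the embedded jump chain, the polarity-asymmetry flag
#' with its orientation, and the noise model.
#'
#' @param name preset identifier.
#' @param states named numeric vector of per-state conductances in nS; names
#'   are state labels (subset of `S0`, `S1`, `S2A`, `S2B`).
#' @param mean_dwell_s named numeric vector of mean sojourn times in seconds,
#'   same names as `states`.
#' @param transition_weights named list; for each state a named numeric vector
#'   of successor weights summing to 1 over the *other* states (empty for a
#'   single-state channel).
#' @param asymmetric logical; if `TRUE` the channel can leave the open state
#'   under one voltage polarity only.
#' @param orientation `+1` or `-1`: the polarity sign under which closure is
#'   permitted (`+1` means closure when V > 0). Required when `asymmetric`.
#' @param noise_sd_pA standard deviation of the additive Gaussian recording
#'   noise at acquisition rate, in pA.
#' @param conductance_sd_nS event-to-event scatter of the realized sojourn
#'   conductance around the state mean, in nS. This reproduces the width of
#'   measured amplitude histograms; set to 0 for exactly ohmic levels.
#' @return object of class `channel_preset`.
#' @export
channel_preset <- function(name, states, mean_dwell_s, transition_weights,
                           asymmetric = FALSE, orientation = NA_integer_,
                           noise_sd_pA = 2, conductance_sd_nS = 0.12) {
  labels <- names(states)
  if (is.null(labels) || anyDuplicated(labels) > 0)
    stop("states must be a named vector with unique state labels")
  if (any(states <= 0)) stop("state conductances must be positive")
  if (!setequal(labels, names(mean_dwell_s)))
    stop("mean_dwell_s must carry the same state labels as states")
  if (any(mean_dwell_s <= 0)) stop("mean dwell times must be positive")
  if (!setequal(labels, names(transition_weights)))
    stop("transition_weights must carry one entry per state")
  for (s in labels) {
    w <- transition_weights[[s]]
    if (length(w) == 0) next
    if (is.null(names(w)) || !all(names(w) %in% labels) || s %in% names(w))
      stop("transition weights of ", s, " must name other registered states")
    if (any(w < 0) || !.near(sum(w), 1))
      stop("transition weights of ", s, " must be non-negative and sum to 1")
  }
  if (isTRUE(asymmetric) && !(isTRUE(orientation %in% c(-1L, 1L))))
    stop("asymmetric presets need orientation +1 or -1")
  structure(
    list(
      name = name,
      states = states[order(-states)],
      mean_dwell_s = mean_dwell_s[names(states[order(-states)])],
      transition_weights = transition_weights,
      asymmetric = isTRUE(asymmetric),
      orientation = if (isTRUE(asymmetric)) as.integer(orientation) else NA_integer_,
      noise_sd_pA = noise_sd_pA,
      conductance_sd_nS = conductance_sd_nS
    ),
    class = "channel_preset"
  )
}

#' Build a registered channel-variant preset
#'
#' @param name one of [list_presets()]: `"native"`, `"cysteinless"`,
#'   `"delta21"`, `"A14C-S193C_ox"`, `"A14C-S193C_red"`, `"V3C-K119C_ox"`,
#'   `"V3C-K119C_red"`.
#' @param ... overrides passed on to [channel_preset()] (e.g. `noise_sd_pA`,
#'   `conductance_sd_nS`, `orientation` together with `asymmetric`).
#' @return a `channel_preset`.
#' @export
#' @examples
#' p <- build_preset("native")
#' state_conductance(p, "S0")  # 3.94 nS
build_preset <- function(name, ...) {
  tab <- .preset_table()
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; registered presets: ",
         paste(names(tab), collapse = ", "))
  }
  spec <- tab[[name]]
  args <- utils::modifyList(
    list(name = name, states = spec$states, mean_dwell_s = spec$mean_dwell_s,
         transition_weights = spec$transition_weights,
         asymmetric = spec$asymmetric, orientation = spec$orientation),
    list(...)
  )
  do.call(channel_preset, args)
}

#' Look up a state conductance in a preset
#' @param preset a `channel_preset`.
#' @param label state label, e.g. `"S0"`.
#' @return conductance in nS.
#' @export
state_conductance <- function(preset, label) {
  if (!label %in% names(preset$states)) {
    stop("preset '", preset$name, "' has no state '", label, "'")
  }
  unname(preset$states[[label]])
}

#' Stationary visit distribution of a preset's jump chain
#' @param preset a `channel_preset`.
#' @return named numeric vector of per-state visit frequencies.
#' @export
visit_frequencies <- function(preset) {
  labels <- names(preset$states)
  k <- length(labels)
  if (k == 1) return(stats::setNames(1, labels))
  P <- matrix(0, k, k, dimnames = list(labels, labels))
  for (s in labels) {
    w <- preset$transition_weights[[s]]
    P[s, names(w)] <- w
  }
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- qr.solve(A, b)
  stats::setNames(pmax(pi_hat, 0) / sum(pmax(pi_hat, 0)), labels)
}

#' Theoretical mean sojourn time of a preset
#'
#' The visit-frequency-weighted mean of the per-state mean dwell times: the
#' expected time spent in one state before switching to the next, matching
#' the "overall dwell time" statistic of [dwell_summary()].
#'
#' @param preset a `channel_preset`.
#' @return mean sojourn in seconds.
#' @export
theoretical_mean_sojourn <- function(preset) {
  pi_hat <- visit_frequencies(preset)
  sum(pi_hat * preset$mean_dwell_s[names(pi_hat)])
}

#' Rescale a preset's dwell means to a target overall mean sojourn
#'
#' Multiplies every per-state mean dwell by a common factor so that
#' [theoretical_mean_sojourn()] equals `overall_mean_s`. Conductances and
#' transition weights are untouched. Useful to pin the simulator to a
#' reported overall dwell time when per-state means and the overall mean
#' were measured on different event sets.
#'
#' @param preset a `channel_preset`.
#' @param overall_mean_s target overall mean sojourn, seconds.
#' @return rescaled `channel_preset`.
#' @export
rescale_dwell_means <- function(preset, overall_mean_s) {
  stopifnot(overall_mean_s > 0)
  f <- overall_mean_s / theoretical_mean_sojourn(preset)
  preset$mean_dwell_s <- preset$mean_dwell_s * f
  preset
}

#' Coerce a plain list (e.g. parsed JSON) to a channel preset
#' @param x a `channel_preset` or a list with the fields of
#'   [channel_preset()].
#' @return a `channel_preset`.
#' @export
as_channel_preset <- function(x) {
  if (inherits(x, "channel_preset")) return(x)
  if (is.character(x) && length(x) == 1) return(build_preset(x))
  if (!is.list(x)) stop("cannot interpret object as a channel preset")
  x$states <- unlist(x$states)
  x$mean_dwell_s <- unlist(x$mean_dwell_s)
  x$transition_weights <- lapply(x$transition_weights, unlist)
  do.call(channel_preset, x)
}

#' Serialize presets to JSON / read them back
#'
#' @param presets list of `channel_preset` objects (default: all registered
#'   presets).
#' @param path output file.
#' @return `presets_to_json` returns `path` invisibly; `presets_from_json`
#'   returns a named list of `channel_preset` objects.
#' @export
presets_to_json <- function(path, presets = lapply(list_presets(), build_preset)) {
  names(presets) <- vapply(presets, `[[`, "", "name")
  payload <- lapply(presets, function(p) {
    list(states = as.list(p$states), mean_dwell_s = as.list(p$mean_dwell_s),
         transition_weights = lapply(p$transition_weights, as.list),
         asymmetric = p$asymmetric, orientation = p$orientation,
         noise_sd_pA = p$noise_sd_pA, conductance_sd_nS = p$conductance_sd_nS)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname presets_to_json
#' @export
presets_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    x$name <- nm
    x$orientation <- if (is.null(x$orientation)) NA_integer_ else x$orientation
    as_channel_preset(x)
  })
  stats::setNames(out, names(raw))
}

#' @export
print.channel_preset <- function(x, ...) {
  cat("<channel_preset>", x$name, "\n")
  cat("  states (nS):",
      paste(sprintf("%s=%.2f", names(x$states), x$states), collapse = ", "), "\n")
  cat("  mean dwell (s):",
      paste(sprintf("%s=%.4g", names(x$mean_dwell_s), x$mean_dwell_s),
            collapse = ", "), "\n")
  cat("  asymmetric:", x$asymmetric,
      if (x$asymmetric) paste0("(orientation ", x$orientation, ")") else "", "\n")
  cat("  noise sd:", x$noise_sd_pA, "pA; conductance scatter:",
      x$conductance_sd_nS, "nS\n")
  invisible(x)
}
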