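# Voltage step protocols: ordered (duration, voltage) steps applied across
# the bilayer. Conductance analysis needs several distinct voltages; the
# recordings this package emulates used steps within +/-10 ... +/-40 mV.

#' Create a voltage step protocol
#'
#' @param duration_s step durations in seconds (all positive).
#' @param voltage_mV applied voltage of each step, mV.
#' @return data.frame of class `voltage_protocol` with columns `duration_s`,
#'   `voltage_mV` and attribute `total_s`.
#' @export
voltage_protocol <- function(duration_s, voltage_mV) {
  if (length(duration_s) == 0) stop("protocol must contain at least one step")
  if (length(duration_s) != length(voltage_mV))
    stop("duration_s and voltage_mV must have the same length")
  if (any(duration_s <= 0)) stop("step durations must be positive")
  out <- data.frame(duration_s = as.numeric(duration_s),
                    voltage_mV = as.numeric(voltage_mV))
  class(out) <- c("voltage_protocol", "data.frame")
  attr(out, "total_s") <- sum(out$duration_s)
  out
}

#' Symmetric voltage step protocol
#'
#' Convenience constructor: one step per voltage, alternating polarity as
#' given, each of the same duration.
#'
#' @param voltages_mV voltages in mV, e.g. `c(10, -10, 20, -20, 40, -40)`.
#' @param step_s duration of each step, seconds.
#' @param cycles number of times the sequence is repeated.
#' @return a `voltage_protocol`.
#' @export
step_protocol <- function(voltages_mV = c(10, -10, 20, -20, 30, -30, 40, -40),
                          step_s = 30, cycles = 1) {
  v <- rep(voltages_mV, cycles)
  voltage_protocol(rep(step_s, length(v)), v)
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat("<voltage_protocol>", nrow(x), "steps,", attr(x, "total_s"), "s total\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Coerce steps to a voltage protocol
#' @param x a `voltage_protocol`, a data.frame with `duration_s`/`voltage_mV`
#'   columns, or a list of `(duration_s, voltage_mV)` pairs.
#' @return a `voltage_protocol`.
#' @export
as_voltage_protocol <- function(x) {
  if (inherits(x, "voltage_protocol")) return(x)
  if (is.data.frame(x)) return(voltage_protocol(x$duration_s, x$voltage_mV))
  if (is.list(x)) {
    dur <- vapply(x, function(s) as.numeric(s$duration_s %||% s[[1]]), 0)
    v <- vapply(x, function(s) as.numeric(s$voltage_mV %||% s[[2]]), 0)
    return(voltage_protocol(dur, v))
  }
  stop("cannot interpret object as a voltage protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# step start times (first at 0) and total duration
.protocol_starts <- function(protocol) {
  c(0, cumsum(protocol$duration_s))[seq_len(nrow(protocol))]
}

#' Voltage applied at given times
#' @param protocol a `voltage_protocol`.
#' @param t_s times in seconds within `[0, total)`.
#' @return voltages in mV.
#' @export
protocol_voltage <- function(protocol, t_s) {
  starts <- .protocol_starts(protocol)
  idx <- findInterval(t_s, starts)
  idx[idx < 1] <- 1
  idx[idx > nrow(protocol)] <- nrow(protocol)
  protocol$voltage_mV[idx]
}

#' Read / write a protocol as CSV
#'
#' Plain CSV with columns `duration_s, voltage_mV`; lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @param protocol a `voltage_protocol` (for writing).
#' @return `read_protocol` returns a `voltage_protocol`;
#'   `write_protocol` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("duration_s", "voltage_mV") %in% names(df)))
    stop("protocol file must have columns duration_s and voltage_mV")
  voltage_protocol(df$duration_s, df$voltage_mV)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  utils::write.csv(as.data.frame(protocol)[c("duration_s", "voltage_mV")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
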