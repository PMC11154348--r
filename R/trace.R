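#' Uniformly sampled time series
#'
#' `sampled_trace()` is the universal currency for time-domain signals in the
#' package: excitation voltages, electrode currents, stimulation envelopes.
#' Sample `i` (0-based) is taken at time `t0 + i / sample_rate`.
#'
#' @param values Numeric vector of sample values (finite).
#' @param sample_rate Sampling rate in samples per second (> 0).
#' @param t0 Time of the first sample, seconds.
#' @param unit Unit label for the values: one of `"mV"`, `"uA"`, `"nA"`,
#'   `"V"`, `"dimensionless"`.
#' @return An object of class `sampled_trace`.
#' @examples
#' tr <- sampled_trace(sin(2 * pi * 5 * (0:99) / 100), sample_rate = 100,
#'                     unit = "dimensionless")
#' head(trace_times(tr))
#' @export
sampled_trace <- function(values, sample_rate, t0 = 0,
                          unit = c("mV", "uA", "nA", "V", "dimensionless")) {
  unit <- match.arg(unit)
  stopifnot_scalar(sample_rate, "sample_rate")
  if (sample_rate <= 0) stop_invalid_spec("sample_rate must be > 0")
  values <- as.numeric(values)
  if (length(values) && any(!is.finite(values)))
    stop_invalid_spec("trace values must be finite")
  structure(list(values = values, sample_rate = sample_rate,
                 t0 = t0, unit = unit),
            class = "sampled_trace")
}

#' Sample times of a trace
#'
#' @param trace A [sampled_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  if (length(trace$values) == 0L) return(numeric(0))
  trace$t0 + (seq_along(trace$values) - 1) / trace$sample_rate
}

#' @export
length.sampled_trace <- function(x) length(x$values)

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %d samples @ %g Hz, unit %s, t0 = %g s\n",
              length(x$values), x$sample_rate, x$unit, x$t0))
  if (length(x$values)) {
    cat(sprintf("  range [%.6g, %.6g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

#' @export
as.data.frame.sampled_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values)
}

#' @export
plot.sampled_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = x$unit, ...)
}

#' Duration covered by a trace
#' @param trace A [sampled_trace()].
#' @return Duration in seconds (`n / sample_rate`).
#' @export
trace_duration <- function(trace) length(trace$values) / trace$sample_rate
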