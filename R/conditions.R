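# Classed conditions shared across the package. Every user-facing error is a
# "headstage_error"; the subclass encodes the failure mode so callers (and the
# CLI) can branch without string matching.

hs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "headstage_error", "error"),
                      call = call))
}

stop_invalid_spec <- function(msg) hs_stop(msg, "headstage_error_invalid_spec")
stop_range        <- function(msg) hs_stop(msg, "headstage_error_range")
stop_insufficient <- function(msg) hs_stop(msg, "headstage_error_insufficient_data")
stop_measurement  <- function(msg) hs_stop(msg, "headstage_error_measurement")
stop_alignment    <- function(msg) hs_stop(msg, "headstage_error_alignment")
stop_format       <- function(msg) hs_stop(msg, "headstage_error_format")
stop_stability    <- function(msg) hs_stop(msg, "headstage_error_stability")
stop_waveform     <- function(msg) hs_stop(msg, "headstage_error_unsupported_waveform")
stop_no_peak      <- function(msg) hs_stop(msg, "headstage_error_no_peak")

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid_spec(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
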