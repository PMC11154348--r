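# Excitation and stimulation waveform synthesis, modelled the way the hardware
# produces them: a DAC stepping through a small sine lookup table under DMA/PWM
# timing (zero-order hold), a triangular sweep for cyclic voltammetry, a
# constant potential for amperometry, and a two-timer optical pulse train.

# DAC output range of the potentiostat waveform generator, mV vs RE.
DAC_RANGE_MV <- c(-1800, 1000)

#' Build a sine lookup table
#'
#' The excitation generator holds a short sine table (26 points in the
#' reference configuration) that a current DAC steps through; the peak code is
#' the programmed DAC current (31.875 uA by default elsewhere in the package)
#' and the bias is the mid-rail offset the single-supply front end requires.
#'
#' @param n_points Number of table entries (>= 4).
#' @param amplitude Peak level above the bias (uA or mV, > 0).
#' @param bias Offset level added to every code.
#' @return An object of class `sine_lut` with fields `codes`, `n_points`,
#'   `amplitude`, `bias`.
#' @examples
#' lut <- build_sine_lut(26, 31.875, 0)
#' max(lut$codes)
#' @export
build_sine_lut <- function(n_points, amplitude, bias = 0) {
  stopifnot_scalar(n_points, "n_points")
  stopifnot_scalar(amplitude, "amplitude")
  if (n_points < 4 || n_points != round(n_points))
    stop_invalid_spec("n_points must be an integer >= 4")
  if (amplitude <= 0) stop_invalid_spec("amplitude must be > 0")
  n_points <- as.integer(n_points)
  # for even table sizes, align the sample grid with the crest so the table
  # holds the exact +/- amplitude codes (a symmetric table); a full period of
  # uniform samples keeps the mean at the bias for any alignment
  phi <- if (n_points %% 2 == 0) {
    pi / 2 - 2 * pi * floor(n_points / 4) / n_points
  } else 0
  codes <- bias +
    amplitude * sin(2 * pi * (seq_len(n_points) - 1) / n_points + phi)
  structure(list(codes = codes, n_points = n_points,
                 amplitude = amplitude, bias = bias),
            class = "sine_lut")
}

#' Plan the dual-PWM excitation timing
#'
#' DMA transactions that clock the DAC through the sine table are timed by a
#' 16-bit PWM divider. A single fast (bus) clock cannot reach low signal
#' frequencies within 16 bits, so a second, slower clock reference is
#' selectable: the fast clock is used whenever its required divider fits in 16
#' bits, otherwise the slow clock. The integer divider quantizes the achieved
#' frequency; a deviation beyond 1 % of the target is surfaced as a
#' quantization warning in the returned plan, never silently dropped.
#'
#' @param target_hz Desired signal frequency (Hz, > 0).
#' @param lut A [build_sine_lut()] table (one period per full table sweep).
#' @param fast_clock_hz,slow_clock_hz Available timer clock references
#'   (fast > slow > 0). Defaults: 24 MHz bus clock, 100 kHz auxiliary clock.
#' @return An object of class `timer_plan` with fields `clock_source`
#'   (`"fast"`/`"slow"`), `clock_hz`, `divider`, `achieved_update_hz`,
#'   `achieved_signal_hz`, and `quantization_warning` (`NULL` or a message).
#' @examples
#' plan_excitation_timing(10, build_sine_lut(26, 31.875))
#' @export
plan_excitation_timing <- function(target_hz, lut,
                                   fast_clock_hz = 24e6,
                                   slow_clock_hz = 100e3) {
  stopifnot_scalar(target_hz, "target_hz")
  if (target_hz <= 0) stop_invalid_spec("target_hz must be > 0")
  if (!(fast_clock_hz > slow_clock_hz && slow_clock_hz > 0))
    stop_invalid_spec("need fast_clock_hz > slow_clock_hz > 0")
  n <- lut$n_points
  max_div <- 2^16 - 1

  pick <- function(clock_hz, source) {
    divider <- round(clock_hz / (n * target_hz))
    if (divider < 1 || divider > max_div) return(NULL)
    update_hz <- clock_hz / divider
    list(clock_source = source, clock_hz = clock_hz, divider = divider,
         achieved_update_hz = update_hz, achieved_signal_hz = update_hz / n)
  }

  plan <- pick(fast_clock_hz, "fast")
  if (is.null(plan)) plan <- pick(slow_clock_hz, "slow")
  if (is.null(plan))
    stop_range(sprintf(
      "target %g Hz unreachable: divider overflows 16 bits on both clocks",
      target_hz))

  rel_err <- abs(plan$achieved_signal_hz - target_hz) / target_hz
  plan$quantization_warning <- if (rel_err > 0.01) {
    sprintf("achieved %.6g Hz deviates %.2f%% from target %g Hz (integer divider %d)",
            plan$achieved_signal_hz, 100 * rel_err, target_hz, plan$divider)
  } else NULL
  class(plan) <- "timer_plan"
  plan
}

#' @export
print.timer_plan <- function(x, ...) {
  cat(sprintf("<timer_plan> %s clock %g Hz / %d -> update %.6g Hz, signal %.6g Hz\n",
              x$clock_source, x$clock_hz, x$divider,
              x$achieved_update_hz, x$achieved_signal_hz))
  if (!is.null(x$quantization_warning))
    cat("  warning:", x$quantization_warning, "\n")
  invisible(x)
}

#' Synthesize a zero-order-hold LUT sine
#'
#' Reproduces the DAC output: the table codes are held piecewise-constant at
#' `n_points * signal_hz` updates per second. The hold steps carry harmonics at
#' `k * n_points +/- 1` times the fundamental; they are retained deliberately so
#' that demodulation systematics are reproducible. The fundamental amplitude is
#' attenuated only by the hold sinc roll-off (0.24 % at 26 points/period).
#'
#' @param lut A [build_sine_lut()] table.
#' @param signal_hz Fundamental frequency (Hz, > 0).
#' @param sample_rate Sampling rate of the rendered trace; must resolve each
#'   hold step (`>= 10 * n_points * signal_hz`).
#' @param duration Trace duration in seconds (>= 0).
#' @param unit Unit label for the trace values.
#' @return A [sampled_trace()].
#' @export
synth_sine <- function(lut, signal_hz, sample_rate, duration, unit = "uA") {
  stopifnot_scalar(signal_hz, "signal_hz")
  stopifnot_scalar(sample_rate, "sample_rate")
  if (signal_hz <= 0) stop_invalid_spec("signal_hz must be > 0")
  if (sample_rate < 10 * lut$n_points * signal_hz)
    stop_invalid_spec(sprintf(
      "sample_rate %g Hz undersamples the hold steps; need >= %g Hz",
      sample_rate, 10 * lut$n_points * signal_hz))
  n_samples <- round(duration * sample_rate)
  if (n_samples <= 0)
    return(sampled_trace(numeric(0), sample_rate, unit = unit))
  t <- (seq_len(n_samples) - 1) / sample_rate
  # index of the LUT code currently held at each sample time
  idx <- floor(t * lut$n_points * signal_hz) %% lut$n_points + 1
  sampled_trace(lut$codes[idx], sample_rate, unit = unit)
}

#' Triangular cyclic-voltammetry waveform specification
#'
#' @param v_start Starting potential, mV.
#' @param v_vertex_low,v_vertex_high Lower/upper switching potentials, mV
#'   (`v_vertex_low < v_vertex_high`); all potentials must lie within the DAC
#'   range -1800..+1000 mV vs RE.
#' @param scan_rate Sweep rate, mV/s (> 0).
#' @param n_cycles Number of full cycles (integer >= 0).
#' @param sample_rate Sampling rate of the rendered trace, Hz.
#' @return An object of class `cv_waveform_spec`.
#' @export
cv_waveform_spec <- function(v_start, v_vertex_low, v_vertex_high,
                             scan_rate, n_cycles = 1, sample_rate = 250) {
  for (nm in c("v_start", "v_vertex_low", "v_vertex_high", "scan_rate"))
    stopifnot_scalar(get(nm), nm)
  if (v_vertex_low >= v_vertex_high)
    stop_invalid_spec("v_vertex_low must be < v_vertex_high")
  if (scan_rate <= 0) stop_invalid_spec("scan_rate must be > 0")
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop_invalid_spec("n_cycles must be an integer >= 0")
  pots <- c(v_start, v_vertex_low, v_vertex_high)
  if (any(pots < DAC_RANGE_MV[1] | pots > DAC_RANGE_MV[2]))
    stop_range(sprintf("potentials must lie within [%d, %d] mV",
                       DAC_RANGE_MV[1], DAC_RANGE_MV[2]))
  if (v_start < v_vertex_low || v_start > v_vertex_high)
    stop_invalid_spec("v_start must lie between the vertices")
  structure(list(v_start = v_start, v_vertex_low = v_vertex_low,
                 v_vertex_high = v_vertex_high, scan_rate = scan_rate,
                 n_cycles = as.integer(n_cycles), sample_rate = sample_rate),
            class = "cv_waveform_spec")
}

#' Synthesize a triangular CV sweep
#'
#' The sweep starts at `v_start` heading toward the nearer vertex, then
#' alternates between the vertices for `n_cycles` full cycles (one cycle =
#' up-sweep + down-sweep, period `2 * (v_vertex_high - v_vertex_low) /
#' scan_rate`). The slope magnitude equals `scan_rate` everywhere and the
#' continuous extrema are exactly the vertices.
#'
#' @param spec A [cv_waveform_spec()].
#' @return A [sampled_trace()] of potential in mV.
#' @export
synth_cv_waveform <- function(spec) {
  if (!inherits(spec, "cv_waveform_spec"))
    stop_invalid_spec("spec must be a cv_waveform_spec")
  if (spec$n_cycles == 0L)
    return(sampled_trace(numeric(0), spec$sample_rate, unit = "mV"))
  span <- spec$v_vertex_high - spec$v_vertex_low
  period <- 2 * span / spec$scan_rate
  # initial direction: toward the nearer vertex (ties go upward)
  up_first <- (spec$v_vertex_high - spec$v_start) <= (spec$v_start - spec$v_vertex_low)
  dir0 <- if (up_first) 1 else -1
  # phase offset of a canonical triangle rising from v_vertex_low at tau = 0
  tau0 <- if (dir0 > 0) (spec$v_start - spec$v_vertex_low) / spec$scan_rate
          else period / 2 + (spec$v_vertex_high - spec$v_start) / spec$scan_rate
  duration <- spec$n_cycles * period
  n <- round(duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  tau <- (t + tau0) %% period
  v <- ifelse(tau <= period / 2,
              spec$v_vertex_low + spec$scan_rate * tau,
              spec$v_vertex_high - spec$scan_rate * (tau - period / 2))
  sampled_trace(v, spec$sample_rate, unit = "mV")
}

#' Synthesize a constant potential
#'
#' The amperometry excitation: a DC potential within the DAC range
#' (-1800..+1000 mV vs RE).
#'
#' @param v_dc Applied potential, mV.
#' @param duration Seconds (>= 0).
#' @param sample_rate Hz.
#' @return A [sampled_trace()] in mV with `round(duration * sample_rate)`
#'   samples, all equal to `v_dc`.
#' @examples
#' length(synth_constant(250, 300, 100))  # 30000 samples at 250 mV
#' @export
synth_constant <- function(v_dc, duration, sample_rate) {
  stopifnot_scalar(v_dc, "v_dc")
  if (v_dc < DAC_RANGE_MV[1] || v_dc > DAC_RANGE_MV[2])
    stop_range(sprintf("v_dc must lie within [%d, %d] mV",
                       DAC_RANGE_MV[1], DAC_RANGE_MV[2]))
  n <- round(duration * sample_rate)
  sampled_trace(rep(v_dc, max(0, n)), sample_rate, unit = "mV")
}

#' Optical pulse-train specification
#'
#' The stimulator's two timer counters set, respectively, the width of the
#' individual light pulses and the overall train duration; `power_setting` is
#' the PWM duty-cycle fraction fed to the laser-diode driver (see
#' [duty_to_current()]; lower duty means higher current).
#'
#' @param n_pulses Number of pulses (integer >= 0).
#' @param pulse_width Pulse duration, seconds (<= `pulse_period`).
#' @param pulse_period Pulse repetition period, seconds.
#' @param power_setting Duty-cycle fraction in `[0, 1]`.
#' @param total_duration Envelope duration, seconds
#'   (default `n_pulses * pulse_period`).
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(n_pulses, pulse_width, pulse_period,
                        power_setting = 0, total_duration = NULL) {
  if (n_pulses < 0 || n_pulses != round(n_pulses))
    stop_invalid_spec("n_pulses must be an integer >= 0")
  if (pulse_width > pulse_period)
    stop_invalid_spec("pulse_width must not exceed pulse_period")
  if (pulse_width <= 0 || pulse_period <= 0)
    stop_invalid_spec("pulse_width and pulse_period must be > 0")
  if (power_setting < 0 || power_setting > 1)
    stop_range("power_setting (duty cycle) must lie in [0, 1]")
  if (is.null(total_duration)) total_duration <- n_pulses * pulse_period
  if (total_duration < n_pulses * pulse_period)
    stop_invalid_spec("total_duration must cover n_pulses * pulse_period")
  structure(list(n_pulses = as.integer(n_pulses), pulse_width = pulse_width,
                 pulse_period = pulse_period, power_setting = power_setting,
                 total_duration = total_duration),
            class = "pulse_train")
}

#' Render a pulse train as a binary envelope
#'
#' @param train A [pulse_train()].
#' @param sample_rate Hz.
#' @return A dimensionless 0/1 [sampled_trace()] with exactly
#'   `train$n_pulses` high intervals of width `pulse_width` starting at
#'   multiples of `pulse_period`.
#' @export
build_pulse_train <- function(train, sample_rate) {
  if (!inherits(train, "pulse_train"))
    stop_invalid_spec("train must be a pulse_train")
  n <- round(train$total_duration * sample_rate)
  v <- numeric(max(0, n))
  if (n > 0 && train$n_pulses > 0) {
    # integer sample arithmetic keeps every pulse exactly round(width * fs)
    # samples long regardless of floating-point representation of the times
    w <- round(train$pulse_width * sample_rate)
    for (k in seq_len(train$n_pulses) - 1) {
      s <- round(k * train$pulse_period * sample_rate)
      if (s >= n) break
      v[(s + 1):min(s + w, n)] <- 1
    }
  }
  sampled_trace(v, sample_rate, unit = "dimensionless")
}
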