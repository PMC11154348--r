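# Digital lock-in amplifier. The hardware flips the polarity of a delta-sigma
# ADC in step with the excitation, i.e. it multiplies the input by a +/-1
# square wave and averages -- a phase-sensitive detector whose in-phase and
# quadrature products isolate the component at the reference frequency (plus
# the odd harmonics a square-wave reference admits). Both the SUT channel and
# the internally measured excitation are demodulated, and the impedance is the
# ratio of the two complex results, so all common gain factors (including the
# analytic 2/pi demodulation factor and the zero-order-hold roll-off) cancel.

#' Demodulator / ADC configuration
#'
#' @param adc_bits ADC resolution in bits (8..24; default 20).
#' @param adc_full_scale ADC input range, volts (inputs clipped to
#'   `+/- adc_full_scale`; default 0.256).
#' @param min_periods Minimum number of whole reference periods averaged per
#'   point (default 10).
#' @param samples_per_period Model samples per reference period (default 260 =
#'   26 hold steps x 10; must resolve each hold step of the excitation).
#' @param r_ref Reference/conversion resistor, Ohm (default 1000): converts the
#'   DAC current to the excitation voltage and the SUT current to the measured
#'   voltage, and scales the channel ratio back to Ohms.
#' @return An object of class `demod_config`.
#' @export
demod_config <- function(adc_bits = 20, adc_full_scale = 0.256,
                         min_periods = 10, samples_per_period = 260,
                         r_ref = 1000) {
  if (adc_bits < 8 || adc_bits > 24)
    stop_invalid_spec("adc_bits must lie in [8, 24]")
  if (min_periods < 1) stop_invalid_spec("min_periods must be >= 1")
  if (r_ref <= 0) stop_invalid_spec("r_ref must be > 0")
  if (adc_full_scale <= 0) stop_invalid_spec("adc_full_scale must be > 0")
  structure(list(adc_bits = as.integer(adc_bits),
                 adc_full_scale = adc_full_scale,
                 min_periods = as.integer(min_periods),
                 samples_per_period = samples_per_period, r_ref = r_ref),
            class = "demod_config")
}

#' Square-wave (polarity-switching) demodulation
#'
#' Multiplies each sample by `sign(sin(2 pi ref_hz t + phase))` and averages
#' over the largest whole number of reference periods the trace covers; a
#' trailing partial period is discarded, mirroring the integer-period state
#' machine of the hardware. For a sine `A sin(2 pi ref_hz t + phi)` the
#' in-phase (0 deg) and quadrature (90 deg) means are `(2 A / pi) cos(phi)` and
#' `(2 A / pi) sin(phi)`; odd harmonics `m` of the reference leak in with
#' weight `1/m`, even harmonics average to zero.
#'
#' @param trace A [sampled_trace()] covering at least `cfg$min_periods`
#'   periods of `ref_hz`.
#' @param ref_hz Reference frequency, Hz.
#' @param phase_shift Reference phase, degrees: 0 (in-phase) or 90
#'   (quadrature).
#' @param cfg A [demod_config()].
#' @return The demodulated mean, with attributes `n_periods` (whole periods
#'   used) and `n_samples`.
#' @export
square_demodulate <- function(trace, ref_hz, phase_shift = 0,
                              cfg = demod_config()) {
  if (!inherits(trace, "sampled_trace"))
    stop_invalid_spec("trace must be a sampled_trace")
  if (!phase_shift %in% c(0, 90))
    stop_invalid_spec("phase_shift must be 0 or 90 degrees")
  fs <- trace$sample_rate
  n_periods <- floor(length(trace$values) / fs * ref_hz + 1e-9)
  if (n_periods < cfg$min_periods)
    stop_insufficient(sprintf(
      "trace covers %d whole periods of %g Hz; need >= %d",
      n_periods, ref_hz, cfg$min_periods))
  n_use <- floor(n_periods * fs / ref_hz + 1e-9)
  t <- trace$t0 + (seq_len(n_use) - 1) / fs
  ref <- sin(2 * pi * ref_hz * t + phase_shift * pi / 180)
  sq <- ifelse(ref >= 0, 1, -1)
  out <- mean(trace$values[seq_len(n_use)] * sq)
  attr(out, "n_periods") <- as.integer(n_periods)
  attr(out, "n_samples") <- as.integer(n_use)
  out
}

#' Model the delta-sigma ADC as a uniform quantizer
#'
#' Values are clipped to `+/- adc_full_scale` and rounded to the nearest of
#' `2^adc_bits` uniform levels (step `2 * full_scale / 2^bits`; about 0.49 uV
#' at 20 bits, +/-0.256 V). Clipping is defined behaviour, reported through the
#' `clip_fraction` attribute rather than an error. The delta-sigma loop itself
#' is not modelled; oversampling and low-pass filtering are represented by the
#' averaging the demodulator already performs.
#'
#' @param trace A [sampled_trace()] in volts.
#' @param cfg A [demod_config()].
#' @return The quantized [sampled_trace()] with attribute `clip_fraction`.
#' @export
quantize_adc <- function(trace, cfg = demod_config()) {
  if (!inherits(trace, "sampled_trace"))
    stop_invalid_spec("trace must be a sampled_trace")
  fsr <- cfg$adc_full_scale
  step <- 2 * fsr / 2^cfg$adc_bits
  clipped <- pmin(pmax(trace$values, -fsr), fsr)
  q <- round(clipped / step) * step
  q <- pmin(pmax(q, -fsr), fsr)
  out <- sampled_trace(q, trace$sample_rate, t0 = trace$t0, unit = "V")
  attr(out, "clip_fraction") <-
    if (length(trace$values)) mean(abs(trace$values) > fsr) else 0
  out
}

# One full lock-in measurement chain at a single frequency. Returns the
# complex impedance. Ratio calibration: Z = r_ref * D_ref / D_meas, where
# D = I + jQ of the reference (excitation) and measured (current * r_ref)
# voltage channels.
lockin_measure_complex <- function(sut, f, cfg, noise_rms = 0,
                                   dac_amplitude_ua = 31.875,
                                   lut_points = 26) {
  oversample <- cfg$samples_per_period / lut_points
  if (oversample < 10)
    stop_invalid_spec("samples_per_period must give >= 10 samples per hold step")
  fs <- cfg$samples_per_period * f
  duration <- cfg$min_periods / f
  # The DAC drive current is programmable (31.875 uA is the lowest of the
  # stock options); a low-|Z| load at full drive would saturate the +/-0.256 V
  # ADC input, so the model steps the drive down (halving, up to 6 times)
  # until neither channel clips. Ratio calibration cancels the drive level.
  for (attempt in 0:6) {
    amp <- dac_amplitude_ua / 2^attempt
    lut <- build_sine_lut(lut_points, amp, 0)
    i_dac <- synth_sine(lut, f, fs, duration, unit = "uA")
    # excitation voltage across the SUT: DAC current through r_ref, in mV
    v_exc <- sampled_trace(i_dac$values * cfg$r_ref / 1000, fs, unit = "mV")
    i_sut <- respond(sut, v_exc, f)                    # uA
    # channel voltages at the ADC input, volts
    v_ref_ch <- v_exc$values / 1000
    v_meas_ch <- i_sut$values * cfg$r_ref / 1e6        # uA * Ohm -> uV -> V
    if (noise_rms > 0) {
      v_ref_ch <- v_ref_ch + stats::rnorm(length(v_ref_ch), 0, noise_rms)
      v_meas_ch <- v_meas_ch + stats::rnorm(length(v_meas_ch), 0, noise_rms)
    }
    # delta-sigma front end: oversample-average over one hold step, which
    # low-pass filters the hold images near 25x/27x the fundamental before
    # quantization; the identical sinc droop on both channels cancels in the
    # ratio (circular filter -- the block is whole periods)
    w <- max(1L, round(oversample))
    kern <- rep(1 / w, w)
    v_ref_ch <- as.numeric(stats::filter(v_ref_ch, kern, circular = TRUE))
    v_meas_ch <- as.numeric(stats::filter(v_meas_ch, kern, circular = TRUE))
    q_ref <- quantize_adc(sampled_trace(v_ref_ch, fs, unit = "V"), cfg)
    q_meas <- quantize_adc(sampled_trace(v_meas_ch, fs, unit = "V"), cfg)
    if ((attr(q_ref, "clip_fraction") > 0 ||
         attr(q_meas, "clip_fraction") > 0) && attempt < 6) next
    d_ref <- complex(real = square_demodulate(q_ref, f, 0, cfg),
                     imaginary = square_demodulate(q_ref, f, 90, cfg))
    d_meas <- complex(real = square_demodulate(q_meas, f, 0, cfg),
                      imaginary = square_demodulate(q_meas, f, 90, cfg))
    # dead excitation: reference demodulates to (numerically) nothing
    if (Mod(d_ref) < 1e-12 || Mod(d_meas) < 1e-15)
      stop_measurement(sprintf("channel demodulated to ~0 at %g Hz", f))
    return(cfg$r_ref * d_ref / d_meas)
  }
}

#' Measure one impedance point through the full instrument model
#'
#' Synthesizes the held-sine excitation, passes it through the system under
#' test, converts the current back to a voltage over the reference resistor,
#' quantizes both channels, demodulates each for in-phase and quadrature
#' components, and forms `Z = r_ref * (I_ref + jQ_ref) / (I_meas + jQ_meas)`
#' -- the ratio of excitation to current channel, which cancels every common
#' gain factor (demodulation constant, hold roll-off, ADC scale).
#'
#' @param sut A [randles_cell()].
#' @param f Frequency, Hz, in (0, 300 kHz].
#' @param cfg A [demod_config()].
#' @param noise_rms Additive Gaussian noise at the ADC input, volts RMS.
#' @return Named list `z_mag` (Ohm), `phase_deg` (degrees in (-180, 180];
#'   capacitive loads are negative).
#' @examples
#' measure_impedance_point(randles_cell(), 1000)
#' @export
measure_impedance_point <- function(sut, f, cfg = demod_config(),
                                    noise_rms = 0) {
  stopifnot_scalar(f, "f")
  if (f <= 0 || f > 300e3) stop_range("f must lie in (0, 300e3] Hz")
  z <- lockin_measure_complex(sut, f, cfg, noise_rms)
  list(z_mag = Mod(z), phase_deg = Arg(z) * 180 / pi)
}

#' Impedance spectrum container
#'
#' @param frequencies Ascending frequencies, Hz.
#' @param z_mag Impedance magnitudes, Ohm (> 0).
#' @param phase_deg Phase angles, degrees in (-180, 180].
#' @param metadata Optional list (configuration snapshot).
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, z_mag, phase_deg,
                               metadata = list()) {
  n <- length(frequencies)
  if (length(z_mag) != n || length(phase_deg) != n)
    stop_invalid_spec("frequencies, z_mag and phase_deg must share a length")
  if (n > 1 && any(diff(frequencies) <= 0))
    stop_format("frequencies must be strictly ascending")
  if (any(z_mag <= 0)) stop_format("z_mag must be > 0")
  if (any(phase_deg <= -180 | phase_deg > 180))
    stop_format("phase_deg must lie in (-180, 180]")
  structure(list(frequencies = as.numeric(frequencies),
                 z_mag = as.numeric(z_mag),
                 phase_deg = as.numeric(phase_deg),
                 metadata = metadata),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("<impedance_spectrum> %d points", length(x$frequencies)))
  if (length(x$frequencies))
    cat(sprintf(", %g Hz .. %g Hz, |Z| %.4g .. %.4g Ohm",
                min(x$frequencies), max(x$frequencies),
                min(x$z_mag), max(x$z_mag)))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, zmag_ohm = x$z_mag,
             phase_deg = x$phase_deg)
}

#' @export
plot.impedance_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$frequencies, x$z_mag, log = "xy", type = "b",
                 xlab = "frequency (Hz)", ylab = "|Z| (Ohm)", ...)
  graphics::plot(x$frequencies, x$phase_deg, log = "x", type = "b",
                 xlab = "frequency (Hz)", ylab = "phase (deg)", ...)
  invisible(x)
}

#' Run a frequency sweep
#'
#' One [measure_impedance_point()] per frequency, each averaging at least
#' `cfg$min_periods` whole periods; deterministic given `seed`.
#'
#' @param sut A [randles_cell()].
#' @param frequencies Ascending frequencies in (0, 300 kHz].
#' @param cfg A [demod_config()].
#' @param noise_rms ADC-input noise, volts RMS.
#' @param seed Integer seed for the noise stream.
#' @return An [impedance_spectrum()].
#' @export
run_sweep <- function(sut, frequencies, cfg = demod_config(),
                      noise_rms = 0, seed = 1L) {
  if (length(frequencies) == 0L)
    return(impedance_spectrum(numeric(0), numeric(0), numeric(0),
                              metadata = list(cfg = cfg, seed = seed)))
  if (any(frequencies <= 0 | frequencies > 300e3))
    stop_range("frequencies must lie in (0, 300e3] Hz")
  if (length(frequencies) > 1 && any(diff(frequencies) <= 0))
    stop_invalid_spec("frequencies must be strictly ascending")
  set.seed(seed)
  zm <- ph <- numeric(length(frequencies))
  for (i in seq_along(frequencies)) {
    pt <- tryCatch(
      measure_impedance_point(sut, frequencies[i], cfg, noise_rms),
      headstage_error = function(e) {
        stop_measurement(sprintf("sweep failed at %g Hz: %s",
                                 frequencies[i], conditionMessage(e)))
      })
    zm[i] <- pt$z_mag
    ph[i] <- pt$phase_deg
  }
  impedance_spectrum(frequencies, zm, ph,
                     metadata = list(cfg = cfg, noise_rms = noise_rms,
                                     seed = seed))
}

#' Relative impedance of a cell-covered vs blank electrode
#'
#' The cell-growth statistic: per frequency,
#' `relative impedance (%) = |Z|_with_cells / |Z|_without_cells x 100`,
#' restricted to the averaging band, plus the unweighted arithmetic mean over
#' the in-band frequencies. Both spectra must share the same frequency grid;
#' no silent interpolation is performed.
#'
#' @param with_cells,without_cells [impedance_spectrum()] objects on the same
#'   grid.
#' @param band Averaging band `c(lo, hi)` in Hz (default 200 Hz .. 300 kHz).
#' @return List with `frequencies` (in-band, Hz), `per_frequency` (percent)
#'   and `band_mean` (percent).
#' @export
relative_impedance <- function(with_cells, without_cells,
                               band = c(200, 300e3)) {
  if (!inherits(with_cells, "impedance_spectrum") ||
      !inherits(without_cells, "impedance_spectrum"))
    stop_invalid_spec("inputs must be impedance_spectrum objects")
  fa <- with_cells$frequencies
  fb <- without_cells$frequencies
  if (length(fa) != length(fb) || any(abs(fa - fb) > 1e-9 * pmax(fa, 1)))
    stop_alignment("spectra are on different frequency grids")
  # tolerate floating-point jitter at the band edges
  in_band <- fa >= band[1] * (1 - 1e-9) & fa <= band[2] * (1 + 1e-9)
  if (!any(in_band))
    stop_insufficient("no frequencies inside the averaging band")
  pct <- 100 * with_cells$z_mag[in_band] / without_cells$z_mag[in_band]
  list(frequencies = fa[in_band], per_frequency = pct,
       band_mean = mean(pct))
}

#' Band-mean relative impedance for every day of a growth study
#'
#' @param study A [generate_growth_study()] result.
#' @param band Averaging band, Hz.
#' @return Named numeric vector of band means (percent), one per day.
#' @export
growth_band_means <- function(study, band = c(200, 300e3)) {
  if (!inherits(study, "growth_study"))
    stop_invalid_spec("study must be a growth_study")
  means <- vapply(study$spectra, function(sp)
    relative_impedance(sp, study$blank, band)$band_mean, numeric(1))
  names(means) <- study$day_labels
  means
}
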