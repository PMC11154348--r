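# Synthetic systems under test: an electrode-electrolyte interface modelled as
# a constant-phase-element (CPE) Randles circuit with a cell-coverage
# mechanism. Cells growing on the electrode insulate it, inhibiting charge
# flux; coverage acts multiplicatively on the charge-transfer resistance,
# which raises |Z| and pushes the phase more negative -- the qualitative
# signature of an ECIS-style growth experiment. The closed-form impedance
# doubles as the oracle for the time-domain lock-in loop.

#' Randles equivalent-circuit system under test
#'
#' Solution resistance `r_s` in series with the parallel combination of the
#' charge-transfer resistance `r_ct` and a constant-phase element
#' `Z_cpe = 1 / (q_dl * (j 2 pi f)^alpha)`. A cell-coverage fraction
#' `theta` in `[0, 1)` scales the charge-transfer path:
#' `r_ct_eff = r_ct / (1 - theta)`.
#'
#' Defaults are fixture values chosen only to keep |Z| in a plausible kilo-ohm
#' band for a culture-well electrode; they carry no measured provenance.
#'
#' @param r_s Solution/series resistance, Ohm (> 0).
#' @param r_ct Charge-transfer resistance, Ohm (> 0).
#' @param q_dl CPE magnitude, S s^alpha (> 0).
#' @param alpha CPE exponent in (0, 1]; `alpha = 1` is an ideal capacitor.
#' @param coverage Cell-coverage fraction theta in `[0, 1)`.
#' @return An object of class `randles_cell`.
#' @examples
#' cell <- randles_cell()
#' randles_impedance(cell, 1000)
#' @export
randles_cell <- function(r_s = 250, r_ct = 1e4, q_dl = 1e-7,
                         alpha = 0.9, coverage = 0) {
  for (nm in c("r_s", "r_ct", "q_dl", "alpha", "coverage"))
    stopifnot_scalar(get(nm), nm)
  if (r_s <= 0 || r_ct <= 0 || q_dl <= 0)
    stop_invalid_spec("r_s, r_ct and q_dl must be > 0")
  if (alpha <= 0 || alpha > 1) stop_invalid_spec("alpha must lie in (0, 1]")
  if (coverage < 0 || coverage >= 1)
    stop_invalid_spec("coverage must lie in [0, 1)")
  structure(list(r_s = r_s, r_ct = r_ct, q_dl = q_dl,
                 alpha = alpha, coverage = coverage),
            class = "randles_cell")
}

#' @export
print.randles_cell <- function(x, ...) {
  cat(sprintf(
    "<randles_cell> Rs = %g Ohm, Rct = %g Ohm, Qdl = %g S s^%g, coverage = %g\n",
    x$r_s, x$r_ct, x$q_dl, x$alpha, x$coverage))
  invisible(x)
}

#' Closed-form impedance of a Randles cell
#'
#' `Z(f) = r_s + 1 / (1/r_ct_eff + q_dl * (j 2 pi f)^alpha)` with
#' `r_ct_eff = r_ct / (1 - coverage)`. At `f = 0` this reduces to
#' `r_s + r_ct_eff`; as `f -> Inf`, `|Z| -> r_s`.
#'
#' @param cell A [randles_cell()].
#' @param f Frequency (Hz, vectorized, >= 0).
#' @return Complex impedance in Ohm (same length as `f`).
#' @export
randles_impedance <- function(cell, f) {
  if (!inherits(cell, "randles_cell"))
    stop_invalid_spec("cell must be a randles_cell")
  if (any(f < 0)) stop_invalid_spec("f must be >= 0")
  r_ct_eff <- cell$r_ct / (1 - cell$coverage)
  jw_a <- complex(modulus = (2 * pi * f)^cell$alpha,
                  argument = rep(pi / 2 * cell$alpha, length(f)))
  z <- cell$r_s + 1 / (1 / r_ct_eff + cell$q_dl * jw_a)
  z[f == 0] <- cell$r_s + r_ct_eff
  z
}

# Admittance used for filtering a real periodic excitation: hermitian in f.
randles_admittance <- function(cell, f) {
  z <- randles_impedance(cell, abs(f))
  y <- 1 / z
  ifelse(f < 0, Conj(y), y)
}

#' Steady-state current response of a Randles cell
#'
#' Filters a (held) sinusoidal excitation voltage through the cell's
#' admittance. The trace is treated as one block of whole periods of the
#' fundamental `f`; every harmonic of the zero-order hold present in the
#' excitation is propagated through `Z` evaluated at that harmonic, up to the
#' Nyquist limit (DFT-domain multiplication by `1/Z(f_k)`).
#'
#' @param cell A [randles_cell()].
#' @param excitation A [sampled_trace()] of voltage in mV spanning a whole
#'   number of periods of `f`.
#' @param f Fundamental frequency of the excitation, Hz.
#' @return A [sampled_trace()] of current in uA
#'   (`i_uA = v_mV / Z_Ohm * 1000`).
#' @export
respond <- function(cell, excitation, f) {
  if (!inherits(excitation, "sampled_trace"))
    stop_invalid_spec("excitation must be a sampled_trace")
  stopifnot_scalar(f, "f")
  if (f <= 0) stop_invalid_spec("f must be > 0")
  n <- length(excitation$values)
  if (n == 0L) return(sampled_trace(numeric(0), excitation$sample_rate, unit = "uA"))
  fs <- excitation$sample_rate
  m <- trace_duration(excitation) * f       # number of fundamental periods
  if (abs(m - round(m)) > 1e-6 || round(m) < 1)
    stop_waveform("excitation must span a whole number of periods of f")
  m <- round(m)
  spec <- stats::fft(excitation$values)
  # all signal energy (DC excluded) must sit at harmonics of the fundamental
  harm <- (seq_len(n) - 1) %% m == 0
  e_tot <- sum(Mod(spec[-1])^2)
  e_off <- sum(Mod(spec[-1][!harm[-1]])^2)
  if (e_tot > 0 && e_off / e_tot > 0.01)
    stop_waveform("excitation is not a (held) sine at frequency f")
  k <- seq_len(n) - 1
  fk <- ifelse(k <= n / 2, k, k - n) * fs / n
  y <- randles_admittance(cell, fk)         # 1/Ohm
  i <- Re(stats::fft(spec * y, inverse = TRUE)) / n
  sampled_trace(i * 1000, fs, t0 = excitation$t0, unit = "uA")  # mV/Ohm -> uA
}

#' Simulate an impedance growth study
#'
#' Emulates a multi-day cell-proliferation experiment: the blank electrode
#' (`coverage = 0`) plus one full lock-in sweep per day at strictly increasing
#' coverage. All sweeps run through the complete instrument model
#' ([run_sweep()]), so quantization and demodulation systematics are included.
#'
#' @param base A [randles_cell()] describing the blank electrode
#'   (its `coverage` is ignored; the blank uses 0).
#' @param schedule Strictly increasing coverage fractions in `[0, 1)`, one per
#'   day. Default: 0.1 .. 0.5 over five days.
#' @param frequencies Sweep frequencies, Hz (ascending). Default: 30
#'   log-spaced points over 10 Hz .. 300 kHz.
#' @param noise_rms ADC-input noise, volts RMS (default 0).
#' @param cfg A [demod_config()].
#' @param seed Integer seed controlling the noise streams.
#' @return An object of class `growth_study`: list with `day_labels`,
#'   `blank` (an `impedance_spectrum`), `spectra` (one per day),
#'   `coverage_schedule`, `seed`.
#' @export
generate_growth_study <- function(base = randles_cell(),
                                  schedule = seq(0.1, 0.5, by = 0.1),
                                  frequencies = log_frequencies(),
                                  noise_rms = 0,
                                  cfg = demod_config(),
                                  seed = 1L) {
  if (length(schedule) < 1 || any(schedule < 0 | schedule >= 1) ||
      (length(schedule) > 1 && any(diff(schedule) <= 0)))
    stop_invalid_spec("schedule must be strictly increasing within [0, 1)")
  blank_cell <- base
  blank_cell$coverage <- 0
  blank <- run_sweep(blank_cell, frequencies, cfg = cfg,
                     noise_rms = noise_rms, seed = seed)
  spectra <- lapply(seq_along(schedule), function(d) {
    cell <- base
    cell$coverage <- schedule[d]
    run_sweep(cell, frequencies, cfg = cfg, noise_rms = noise_rms,
              seed = seed + d)
  })
  structure(list(day_labels = paste0("day", seq_along(schedule)),
                 blank = blank, spectra = spectra,
                 coverage_schedule = schedule, seed = seed),
            class = "growth_study")
}

#' Log-spaced sweep frequencies
#'
#' @param fmin,fmax Band edges, Hz.
#' @param n Number of points.
#' @return Ascending frequency vector, Hz.
#' @export
log_frequencies <- function(fmin = 10, fmax = 300e3, n = 30) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}
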