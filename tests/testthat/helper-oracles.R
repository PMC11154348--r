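# Independent oracles and fixture builders shared across the suite.

# Direct numeric integration of x(t) * sign(sin(2 pi f t + phase)) over m
# whole periods -- the reference for the square-wave demodulator.
demod_oracle <- function(xfun, f, phase_deg = 0, m = 1, n = 200000) {
  t <- (seq_len(n) - 0.5) / n * (m / f)
  ref <- sin(2 * pi * f * t + phase_deg * pi / 180)
  mean(xfun(t) * ifelse(ref >= 0, 1, -1))
}

# Near-ideal resistor / capacitor as degenerate Randles cells.
resistor_cell <- function(r = 1000) {
  randles_cell(r_s = r - 1, r_ct = 1, q_dl = 1e-12, alpha = 1)
}
capacitor_cell <- function(c_f = 1e-6) {
  randles_cell(r_s = 1e-3, r_ct = 1e9, q_dl = c_f, alpha = 1)
}

# Plain sine rendered as a trace.
sine_trace <- function(amp, f, fs, duration, phase = 0, unit = "V") {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  sampled_trace(amp * sin(2 * pi * f * t + phase), fs, unit = unit)
}

default_cv_wave <- function(scan_rate = 50, e0 = 0) {
  cv_waveform_spec(e0 - 300, e0 - 300, e0 + 300, scan_rate)
}
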