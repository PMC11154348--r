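test_that("square-wave demodulation matches the numeric-integration oracle", {
  f <- 50
  fs <- 260 * f
  tr <- sine_trace(1, f, fs, 20 / f)
  cfg <- demod_config()

  oracle_i <- demod_oracle(function(t) sin(2 * pi * f * t), f, 0)
  expect_equal(as.numeric(square_demodulate(tr, f, 0, cfg)), oracle_i,
               tolerance = 1e-4)
  expect_equal(oracle_i, 2 / pi, tolerance = 1e-4)
  # quadrature null to the 0.5% oracle-equivalence level (finite sampling
  # leaves an O(1/N) residue at the square-wave sign flips)
  expect_lt(abs(as.numeric(square_demodulate(tr, f, 90, cfg))),
            0.005 * 2 / pi)

  # (I, Q) = (2A/pi)(cos phi, sin phi) for arbitrary amplitude and phase
  for (phi in c(-2.1, -0.4, 0.9, 2.8)) {
    trp <- sine_trace(3.7, f, fs, 15 / f, phase = phi)
    i <- as.numeric(square_demodulate(trp, f, 0, cfg))
    q <- as.numeric(square_demodulate(trp, f, 90, cfg))
    expect_equal(i, 2 * 3.7 / pi * cos(phi), tolerance = 0.005 * 3.7)
    expect_equal(q, 2 * 3.7 / pi * sin(phi), tolerance = 0.005 * 3.7)
  }
})

test_that("square-wave demodulation weights odd harmonics by 1/m and rejects even ones", {
  f <- 50
  fs <- 260 * f * 3
  cfg <- demod_config()
  tr3 <- sine_trace(1, 3 * f, fs, 12 / f)
  expect_equal(abs(as.numeric(square_demodulate(tr3, f, 0, cfg))),
               (2 / pi) / 3, tolerance = 1e-3)
  tr2 <- sine_trace(1, 2 * f, fs, 12 / f)
  expect_lt(abs(as.numeric(square_demodulate(tr2, f, 0, cfg))), 1e-3)
  tr4 <- sine_trace(1, 4 * f, fs, 12 / f)
  expect_lt(abs(as.numeric(square_demodulate(tr4, f, 0, cfg))), 1e-3)
})

test_that("demodulation discards partial periods and enforces min_periods", {
  f <- 50
  fs <- 260 * f
  cfg <- demod_config(min_periods = 10)
  # 10.6 periods available: uses 10 whole ones
  tr <- sine_trace(1, f, fs, 10.6 / f)
  d <- square_demodulate(tr, f, 0, cfg)
  expect_identical(attr(d, "n_periods"), 10L)
  expect_identical(attr(d, "n_samples"), as.integer(10 * fs / f))

  short <- sine_trace(1, f, fs, 9.5 / f)
  expect_error(square_demodulate(short, f, 0, cfg),
               class = "headstage_error_insufficient_data")
})

test_that("ADC quantizer clips at full scale and uses 2^bits uniform levels", {
  cfg <- demod_config()
  tr <- sampled_trace(c(0, 0.5, -0.5, 1e-4), 100, unit = "V")
  q <- quantize_adc(tr, cfg)
  expect_identical(q$values[1], 0)
  expect_equal(q$values[2], 0.256)
  expect_equal(q$values[3], -0.256)
  expect_equal(attr(q, "clip_fraction"), 0.5)

  step <- 0.512 / 2^20
  expect_equal(step, 4.8828125e-07)
  expect_equal(q$values[4], round(1e-4 / step) * step)
  # half a step rounds to a neighbouring level
  tr2 <- sampled_trace(0.4 * step, 100, unit = "V")
  expect_equal(quantize_adc(tr2, cfg)$values, 0)
})

test_that("lock-in impedance matches closed forms for resistor and capacitor", {
  for (f in c(20, 1000, 50e3)) {
    m <- measure_impedance_point(resistor_cell(1000), f)
    expect_equal(m$z_mag, 1000, tolerance = 0.01)
    expect_equal(m$phase_deg, 0, tolerance = 1)
  }
  c_f <- 1e-6
  for (f in c(100, 1000, 10e3)) {
    m <- measure_impedance_point(capacitor_cell(c_f), f)
    expect_equal(m$z_mag, 1 / (2 * pi * f * c_f), tolerance = 0.01)
    expect_equal(m$phase_deg, -90, tolerance = 1)
  }
})

test_that("lock-in impedance tracks the Randles closed form within 2% over the band", {
  cell <- randles_cell(r_s = 100, r_ct = 10e3, q_dl = 1e-6, alpha = 1)
  for (f in log_frequencies(10, 300e3, 12)) {
    m <- measure_impedance_point(cell, f)
    z <- randles_impedance(cell, f)
    expect_equal(m$z_mag, Mod(z), tolerance = 0.02)
    expect_equal(m$phase_deg, Arg(z) * 180 / pi, tolerance = 2)
    # passive RC network: phase in [-90, 0]
    expect_true(m$phase_deg <= 0.5 && m$phase_deg >= -90.5)
  }
})

test_that("ratio calibration is invariant to a common channel gain", {
  f <- 100
  fs <- 260 * f
  cfg <- demod_config()
  ref <- sine_trace(0.03, f, fs, 10 / f)
  meas <- sine_trace(0.011, f, fs, 10 / f, phase = -0.7)
  ratio_of <- function(g) {
    r <- sampled_trace(g * ref$values, fs, unit = "V")
    m <- sampled_trace(g * meas$values, fs, unit = "V")
    dr <- complex(real = square_demodulate(r, f, 0, cfg),
                  imaginary = square_demodulate(r, f, 90, cfg))
    dm <- complex(real = square_demodulate(m, f, 0, cfg),
                  imaginary = square_demodulate(m, f, 90, cfg))
    dr / dm
  }
  expect_equal(ratio_of(1), ratio_of(7.3), tolerance = 1e-12)
})

test_that("sweeps are deterministic under a seed and flat for a resistor", {
  expect_length(run_sweep(resistor_cell(), numeric(0))$frequencies, 0L)

  fr <- log_frequencies(10, 300e3, 8)
  sp <- run_sweep(resistor_cell(1000), fr, noise_rms = 1e-5, seed = 42)
  expect_true(all(abs(sp$z_mag / 1000 - 1) < 0.01))

  sp2 <- run_sweep(resistor_cell(1000), fr, noise_rms = 1e-5, seed = 42)
  expect_identical(sp$z_mag, sp2$z_mag)
  expect_identical(sp$phase_deg, sp2$phase_deg)

  expect_error(run_sweep(resistor_cell(), c(10, 400e3)),
               class = "headstage_error_range")
})

test_that("more averaging periods never increases measurement variance", {
  f <- 1000
  reps <- 25
  vars <- vapply(c(10, 40), function(mp) {
    cfg <- demod_config(min_periods = mp)
    set.seed(99)
    stats::var(vapply(seq_len(reps), function(i)
      measure_impedance_point(randles_cell(), f, cfg,
                              noise_rms = 2e-5)$z_mag, numeric(1)))
  }, numeric(1))
  expect_lte(vars[2], vars[1])
})

test_that("relative impedance ratios and band mean behave as a growth statistic", {
  fr <- log_frequencies(100, 300e3, 10)
  sp <- impedance_spectrum(fr, rep(2000, 10), rep(-10, 10))
  same <- relative_impedance(sp, sp)
  expect_true(all(same$per_frequency == 100))
  expect_equal(same$band_mean, 100)

  up <- impedance_spectrum(fr, 1.2 * sp$z_mag, sp$phase_deg)
  expect_equal(relative_impedance(up, sp)$band_mean, 120, tolerance = 1e-12)

  # band restriction: 100 Hz point is outside 200 Hz - 300 kHz
  expect_length(relative_impedance(sp, sp)$frequencies, sum(fr >= 200))

  other <- impedance_spectrum(fr * 1.5, sp$z_mag, sp$phase_deg)
  expect_error(relative_impedance(other, sp),
               class = "headstage_error_alignment")
})
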