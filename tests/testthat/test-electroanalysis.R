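test_that("Savitzky-Golay smoothing preserves polynomials and damps noise", {
  fs <- 100
  const <- sampled_trace(rep(4.2, 200), fs, unit = "nA")
  expect_equal(savgol_smooth(const)$values, const$values, tolerance = 1e-12)

  # cubic signal, order-3 filter: reproduced exactly, edges included;
  # oracle: direct local least-squares fit at an interior sample
  t <- (0:199) / fs
  poly <- 2 + 3 * t - 1.5 * t^2 + 0.4 * t^3
  tr <- sampled_trace(poly, fs, unit = "nA")
  sm <- savgol_smooth(tr, window = 11, polyorder = 3)
  expect_equal(sm$values, poly, tolerance = 1e-9)
  i <- 100
  idx <- (i - 5):(i + 5)
  fit <- stats::lm(y ~ stats::poly(x, 3, raw = TRUE),
                   data = data.frame(x = idx - i, y = poly[idx]))
  expect_equal(sm$values[i], unname(stats::predict(fit)[6]), tolerance = 1e-9)

  set.seed(31)
  noise <- sampled_trace(stats::rnorm(2000), fs, unit = "nA")
  expect_lt(stats::var(savgol_smooth(noise)$values),
            stats::var(noise$values))

  expect_error(savgol_smooth(const, window = 10),
               class = "headstage_error_invalid_spec")
  expect_error(savgol_smooth(const, window = 11, polyorder = 11),
               class = "headstage_error_invalid_spec")
})

test_that("CV peak extraction recovers constructed extrema and refuses monotone traces", {
  # synthetic double-Gaussian current over a triangle: known peak locations
  wf <- cv_waveform_spec(-300, -300, 300, 50, sample_rate = 100)
  pot <- synth_cv_waveform(wf)
  half <- length(pot$values) / 2
  dirn <- c(rep(1, half), rep(-1, half))
  cur <- dirn * exp(-(pot$values - dirn * 40)^2 / (2 * 50^2))
  cv <- cv_trace(pot$values, cur, 50)
  pk <- find_cv_peaks(cv)
  expect_equal(pk$anodic_potential, 40, tolerance = 0.5)
  expect_equal(pk$cathodic_potential, -40, tolerance = 0.5)

  lin <- cv_trace(pot$values, 0.01 * pot$values, 50)
  expect_error(find_cv_peaks(lin), class = "headstage_error_no_peak")
})

test_that("peak separation reproduces the worked examples and its symmetries", {
  expect_equal(peak_separation(list(anodic_potential = 85,
                                    cathodic_potential = -85)), 170)
  expect_equal(peak_separation(list(anodic_potential = 240,
                                    cathodic_potential = 130)), 110)
  expect_equal(peak_separation(list(anodic_potential = 155,
                                    cathodic_potential = 75)), 80)
  expect_equal(peak_separation(list(anodic_potential = 165,
                                    cathodic_potential = 70)), 95)
  expect_equal(peak_separation(list(anodic_potential = 50,
                                    cathodic_potential = 50)), 0)
  # symmetric in its arguments and invariant under a common offset
  for (pair in list(c(85, -85), c(240, 130))) {
    expect_equal(peak_separation(list(anodic_potential = pair[1],
                                      cathodic_potential = pair[2])),
                 peak_separation(list(anodic_potential = pair[2],
                                      cathodic_potential = pair[1])))
    expect_equal(peak_separation(list(anodic_potential = pair[1] + 37,
                                      cathodic_potential = pair[2] + 37)),
                 peak_separation(list(anodic_potential = pair[1],
                                      cathodic_potential = pair[2])))
  }
})

test_that("spike detector recovers programmed amplitudes on clean traces", {
  spec <- exocytosis_spec(spike_amp_mean = 60, spike_amp_sd = 10,
                          decay_tau = 1.0, noise_sd = 0)
  proto <- stimulus_protocol(c(30, 60, 90), rep("high_K", 3))
  tr <- simulate_exocytosis_trace(spec, proto, 120, seed = 17)
  gt <- attr(tr, "ground_truth")
  res <- detect_spikes(tr, baseline_window = 20)
  expect_identical(res$stats$n_events, 3L)
  recovered <- res$events$amplitude[order(res$events$t_peak)]
  expect_equal(recovered, gt$amplitude, tolerance = 0.02)
  expect_true(all(res$events$width_half_max > 0))
})

test_that("spike detection is equivariant to baseline shifts", {
  tr <- simulate_exocytosis_trace(exocytosis_spec(), chemical_protocol(),
                                  300, seed = 23)
  shifted <- sampled_trace(tr$values + 50, tr$sample_rate, unit = "nA")
  a <- detect_spikes(tr)
  b <- detect_spikes(shifted)
  expect_identical(a$events$t_peak, b$events$t_peak)
  expect_equal(a$events$amplitude, b$events$amplitude, tolerance = 1e-9)
})

test_that("flat noisy baselines produce no false events at k = 5", {
  # ten minutes at 100 Hz across several seeds: fewer than 1 false positive
  # per 10 min on average
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    tr <- sampled_trace(stats::rnorm(60000, 0, 1), 100, unit = "nA")
    detect_spikes(tr)$stats$n_events
  }, integer(1))
  expect_lt(mean(hits), 1)

  short <- sampled_trace(stats::rnorm(50), 100, unit = "nA")
  expect_error(detect_spikes(short),
               class = "headstage_error_insufficient_data")
})

test_that("fast-scan throughput arithmetic", {
  expect_identical(fscv_throughput(10, 1), 36000)
  expect_identical(fscv_throughput(0, 5), 0)
  expect_identical(fscv_throughput(1, 1), 3600)
  expect_identical(fscv_throughput(10, 0.5), 18000)
  expect_error(fscv_throughput(-1, 1), class = "headstage_error_invalid_spec")
})
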