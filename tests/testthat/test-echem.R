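test_that("reversible CV reproduces the ideal 57/n mV peak separation", {
  wf <- default_cv_wave(50)
  cv1 <- simulate_cv(redox_couple(n_electrons = 1), electrode_spec(), wf)
  sep1 <- peak_separation(find_cv_peaks(cv1))
  expect_equal(sep1, 57, tolerance = 3 / 57)

  cv2 <- simulate_cv(redox_couple(n_electrons = 2), electrode_spec(), wf)
  sep2 <- peak_separation(find_cv_peaks(cv2))
  expect_equal(sep2, 28.5, tolerance = 2 / 28.5)

  # anodic peak sits past E0 on the forward sweep, cathodic before it
  pk <- find_cv_peaks(cv1)
  expect_gt(pk$anodic_potential, pk$cathodic_potential)
  expect_gt(pk$anodic_current, 0)
  expect_lt(pk$cathodic_current, 0)
})

test_that("CV simulator conserves material and responds to nothing without analyte", {
  wf <- default_cv_wave(50)
  cv <- simulate_cv(redox_couple(), electrode_spec(), wf)
  expect_equal(attr(cv, "mass_balance"), 1, tolerance = 1e-3)

  blank <- simulate_cv(redox_couple(bulk_conc = 0), electrode_spec(), wf)
  expect_lt(max(abs(blank$current)), 1e-9)
})

test_that("peak current follows the Randles-Sevcik square-root scan-rate law", {
  v <- 25
  cv_v <- simulate_cv(redox_couple(), electrode_spec(), default_cv_wave(v))
  cv_4v <- simulate_cv(redox_couple(), electrode_spec(), default_cv_wave(4 * v))
  ratio <- find_cv_peaks(cv_4v)$anodic_current /
    find_cv_peaks(cv_v)$anodic_current
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("peak potential is concentration-independent, peak current linear in it", {
  wf <- default_cv_wave(50)
  concs <- c(0.5e-6, 1e-6, 2e-6)
  pks <- lapply(concs, function(cb)
    find_cv_peaks(simulate_cv(redox_couple(bulk_conc = cb),
                              electrode_spec(), wf)))
  pots <- vapply(pks, `[[`, numeric(1), "anodic_potential")
  curs <- vapply(pks, `[[`, numeric(1), "anodic_current")
  expect_lt(max(pots) - min(pots), 1)                 # within 1 mV
  expect_equal(curs[2] / curs[1], 2, tolerance = 0.01)
  expect_equal(curs[3] / curs[2], 2, tolerance = 0.01)
})

test_that("CV simulator guards its stability limit and preconditions", {
  wf <- default_cv_wave(50)
  err <- tryCatch(simulate_cv(redox_couple(), electrode_spec(), wf,
                              n_space = 2000),
                  headstage_error_stability = function(e) e)
  expect_s3_class(err, "headstage_error_stability")
  expect_match(conditionMessage(err), "t_step <=")

  narrow <- cv_waveform_spec(-100, -100, 100, 50)
  expect_error(simulate_cv(redox_couple(), electrode_spec(), narrow),
               class = "headstage_error_invalid_spec")
  expect_error(simulate_cv(redox_couple(reversible = FALSE),
                           electrode_spec(), wf),
               class = "headstage_error_invalid_spec")
})

test_that("chemical protocol yields one spike per high-K injection and none at the control", {
  tr <- simulate_exocytosis_trace(exocytosis_spec(), chemical_protocol(),
                                  duration = 300, seed = 5)
  gt <- attr(tr, "ground_truth")
  expect_identical(nrow(gt), 3L)
  expect_true(all(gt$kind == "high_K"))

  res <- detect_spikes(savgol_smooth(tr))
  expect_identical(res$stats$n_events, 3L)
  expect_false(any(abs(res$events$t_peak - 60) < 5))
  # each detected spike sits near one programmed onset
  expect_true(all(vapply(res$events$t_peak,
                         function(tp) min(abs(tp - gt$onset)) < 2,
                         logical(1))))
})

test_that("five-pulse light trains deplete: amplitudes strictly decrease", {
  tr <- simulate_exocytosis_trace(exocytosis_spec(spike_amp_mean = 82.2),
                                  light_train_protocol(5),
                                  duration = 80, seed = 2)
  gt <- attr(tr, "ground_truth")
  expect_identical(gt$pulse, 1:5)
  expect_true(all(diff(gt$amplitude) < 0))
  expect_equal(gt$amplitude[2] / gt$amplitude[1], 0.8, tolerance = 1e-9)

  res <- detect_spikes(savgol_smooth(tr))
  expect_identical(res$stats$n_events, 5L)
  expect_true(all(diff(res$events$amplitude) < 0))
})

test_that("spike generator is seeded and degrades gracefully", {
  a <- simulate_exocytosis_trace(exocytosis_spec(), chemical_protocol(),
                                 300, seed = 9)
  b <- simulate_exocytosis_trace(exocytosis_spec(), chemical_protocol(),
                                 300, seed = 9)
  expect_identical(a$values, b$values)

  empty <- simulate_exocytosis_trace(exocytosis_spec(),
                                     stimulus_protocol(numeric(0), character(0)),
                                     duration = 120, seed = 1)
  expect_null(attr(empty, "ground_truth"))
  expect_identical(detect_spikes(empty)$stats$n_events, 0L)

  crowded <- stimulus_protocol(c(10, 10.05), c("high_K", "high_K"))
  tr <- simulate_exocytosis_trace(exocytosis_spec(), crowded, 30, seed = 1)
  expect_match(attr(tr, "overlap_warning"), "rise_tau")

  expect_error(simulate_exocytosis_trace(exocytosis_spec(),
                                         chemical_protocol(), duration = 100),
               class = "headstage_error_invalid_spec")
})

test_that("TIA conversion is affine below saturation with a sensitivity flag", {
  # 10 nA through 10 MOhm -> 0.1 V magnitude
  tr <- sampled_trace(rep(10, 4), 100, unit = "nA")
  v <- tia_convert(tr, tia_config(feedback_r = 1e7))
  expect_equal(v$values, rep(-0.1, 4))
  expect_false(attr(v, "saturated"))

  # 25 uA through 10 kOhm -> 0.25 V, inside the CV-mode range
  cv_i <- sampled_trace(25, 100, unit = "uA")
  expect_equal(abs(tia_convert(cv_i, tia_config(feedback_r = 1e4))$values), 0.25)

  # below the 20 pA floor: reported but flagged
  tiny <- sampled_trace(c(10e-3, 50e-3), 100, unit = "nA")  # 10 pA, 50 pA
  flags <- attr(tia_convert(tiny, tia_config(feedback_r = 1e7)), "below_sensitivity")
  expect_identical(flags, c(TRUE, FALSE))

  # exact affinity below saturation; clipping above
  i <- sampled_trace(seq(-100, 100, by = 25), 10, unit = "nA")
  cfg <- tia_config(feedback_r = 1e7, v_sat = 0.8)
  out <- tia_convert(i, cfg)
  expect_equal(out$values, pmin(pmax(-1e7 * i$values * 1e-9, -0.8), 0.8))
  expect_true(attr(out, "saturated"))
})
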