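# Potentiostat-side simulators: 1-D finite-difference cyclic voltammetry of a
# reversible (Nernstian) redox couple, a phenomenological exocytosis spike
# generator for chemical (high-K+) and optical stimulation protocols, and the
# transimpedance-amplifier conversion stage with saturation.

FARADAY_C_MOL <- 96485     # C/mol
GAS_R <- 8.314             # J/(mol K)
TEMP_K <- 298.15

#' Redox couple description
#'
#' Defaults describe a ferri-/ferrocyanide-like couple: one-electron,
#' D = 7.6e-6 cm^2/s, 1 mM bulk. Dopamine oxidation (two electrons) is the
#' other canonical instance. Only the reversible (Nernstian) limit is
#' simulated.
#'
#' @param e0 Formal potential, mV vs RE.
#' @param n_electrons Electrons transferred (integer >= 1).
#' @param diffusion_coeff Diffusion coefficient, cm^2/s (equal for both forms).
#' @param bulk_conc Bulk concentration of the reduced form, mol/cm^3
#'   (1 mM = 1e-6 mol/cm^3).
#' @param reversible Must be `TRUE`; quasi-reversible kinetics are not
#'   modelled.
#' @return An object of class `redox_couple`.
#' @export
redox_couple <- function(e0 = 0, n_electrons = 1, diffusion_coeff = 7.6e-6,
                         bulk_conc = 1e-6, reversible = TRUE) {
  if (n_electrons < 1 || n_electrons != round(n_electrons))
    stop_invalid_spec("n_electrons must be an integer >= 1")
  if (diffusion_coeff <= 0) stop_invalid_spec("diffusion_coeff must be > 0")
  if (bulk_conc < 0) stop_invalid_spec("bulk_conc must be >= 0")
  structure(list(e0 = e0, n_electrons = as.integer(n_electrons),
                 diffusion_coeff = diffusion_coeff, bulk_conc = bulk_conc,
                 reversible = isTRUE(reversible)),
            class = "redox_couple")
}

#' Working-electrode description
#'
#' @param area Electrode area, mm^2 (default 12.56, the culture-well working
#'   electrode of the modelled platform).
#' @param material Label only: `"carbon"`, `"gold"` or `"platinum"`.
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(area = 12.56,
                           material = c("carbon", "gold", "platinum")) {
  material <- match.arg(material)
  if (area <= 0) stop_invalid_spec("area must be > 0")
  structure(list(area = area, material = material), class = "electrode_spec")
}

#' Cyclic voltammogram container
#'
#' @param potential Applied potential, mV (triangular trajectory).
#' @param current Current, uA (anodic/oxidation positive).
#' @param scan_rate Scan rate, mV/s.
#' @return An object of class `cv_trace`.
#' @export
cv_trace <- function(potential, current, scan_rate) {
  if (length(potential) != length(current))
    stop_invalid_spec("potential and current must share a length")
  structure(list(potential = as.numeric(potential),
                 current = as.numeric(current), scan_rate = scan_rate),
            class = "cv_trace")
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("<cv_trace> %d samples, %g .. %g mV at %g mV/s\n",
              length(x$potential), min(x$potential), max(x$potential),
              x$scan_rate))
  invisible(x)
}

#' @export
plot.cv_trace <- function(x, ...) {
  graphics::plot(x$potential, x$current, type = "l",
                 xlab = "potential (mV)", ylab = "current (uA)", ...)
}

#' Simulate a reversible cyclic voltammogram
#'
#' Explicit finite-difference solution of 1-D semi-infinite diffusion with a
#' Nernstian surface equilibrium and equal diffusion coefficients for the
#' oxidized and reduced forms. Only the reduced form is present initially, so
#' the forward (positive-going) sweep produces the anodic peak. The far wall
#' is reflecting and placed six diffusion lengths out, so total material in
#' the grid is conserved. Current is computed from the surface concentration
#' gradient (`i = n F A D dC_R/dx`, oxidation positive) and returned in uA.
#'
#' For a reversible couple at 298 K the anodic-to-cathodic peak separation
#' approaches the ideal 57/n mV when the vertices lie far beyond the peaks.
#'
#' @param couple A [redox_couple()]; must be reversible, and the vertices must
#'   bracket `e0` by at least `150/n` mV on each side.
#' @param electrode An [electrode_spec()].
#' @param waveform A [cv_waveform_spec()].
#' @param n_space Number of spatial grid points (default 300).
#' @param t_step Time step, s (default `0.2 mV / scan_rate`, i.e. 0.2 mV of
#'   potential resolution). The explicit scheme requires
#'   `D t_step / dx^2 <= 0.5`; an unstable grid raises a stability error with
#'   a suggested `t_step`.
#' @return A [cv_trace()] (first full cycle).
#' @export
simulate_cv <- function(couple, electrode, waveform,
                        n_space = 300, t_step = NULL) {
  if (!inherits(couple, "redox_couple"))
    stop_invalid_spec("couple must be a redox_couple")
  if (!couple$reversible)
    stop_invalid_spec("only reversible couples are simulated")
  n <- couple$n_electrons
  margin <- 150 / n
  if (waveform$v_vertex_high < couple$e0 + margin ||
      waveform$v_vertex_low > couple$e0 - margin)
    stop_invalid_spec(sprintf(
      "vertices must bracket e0 by >= %g mV on each side", margin))
  if (is.null(t_step)) t_step <- 0.2 / waveform$scan_rate
  wf <- waveform
  wf$sample_rate <- 1 / t_step
  wf$n_cycles <- 1L
  pot <- synth_cv_waveform(wf)          # mV, one full cycle
  e_mv <- pot$values
  n_t <- length(e_mv)
  d <- couple$diffusion_coeff
  t_total <- n_t * t_step
  l_domain <- 6 * sqrt(d * t_total)     # cm; wide vs the diffusion layer
  dx <- l_domain / (n_space - 1)
  lambda <- d * t_step / dx^2
  if (lambda > 0.5)
    stop_stability(sprintf(
      "explicit scheme unstable (D dt/dx^2 = %.3f > 0.5); use t_step <= %.3g s",
      lambda, 0.5 * dx^2 / d))

  c_r <- rep(couple$bulk_conc, n_space)
  c_o <- rep(0, n_space)
  f_rt <- FARADAY_C_MOL / (GAS_R * TEMP_K)   # 1/V
  area_cm2 <- electrode$area / 100           # mm^2 -> cm^2
  cur <- numeric(n_t)
  idx <- 2:(n_space - 1)
  for (k in seq_len(n_t)) {
    # diffusion update, reflecting far wall
    c_r_new <- c_r
    c_o_new <- c_o
    c_r_new[idx] <- c_r[idx] + lambda * (c_r[idx + 1] - 2 * c_r[idx] + c_r[idx - 1])
    c_o_new[idx] <- c_o[idx] + lambda * (c_o[idx + 1] - 2 * c_o[idx] + c_o[idx - 1])
    c_r_new[n_space] <- c_r[n_space] + lambda * (c_r[n_space - 1] - c_r[n_space])
    c_o_new[n_space] <- c_o[n_space] + lambda * (c_o[n_space - 1] - c_o[n_space])
    # Nernstian surface: C_O(0)/C_R(0) = xi; equal-D flux balance conserves
    # C_O(0) + C_R(0) = C_O(dx) + C_R(dx)
    xi <- exp(n * f_rt * (e_mv[k] - couple$e0) / 1000)
    s <- c_o_new[2] + c_r_new[2]
    c_r_new[1] <- s / (1 + xi)
    c_o_new[1] <- s - c_r_new[1]
    c_r <- c_r_new
    c_o <- c_o_new
    # oxidation current from the R gradient at the surface (second-order
    # one-sided difference), A -> uA
    grad <- (-3 * c_r[1] + 4 * c_r[2] - c_r[3]) / (2 * dx)
    cur[k] <- n * FARADAY_C_MOL * area_cm2 * d * grad * 1e6
  }
  out <- cv_trace(e_mv, cur, waveform$scan_rate)
  attr(out, "grid") <- list(n_space = n_space, t_step = t_step,
                            lambda = lambda, n_t = n_t)
  attr(out, "mass_balance") <- sum(c_r + c_o) / (n_space * couple$bulk_conc)
  out
}

#' Exocytosis spike-train specification
#'
#' Phenomenology of stimulated dopamine release recorded by constant-potential
#' amperometry on a large (many-cell) electrode: each stimulus produces one
#' composite current spike (difference of exponentials), and within a pulse
#' train the releasable vesicle pool depletes, shrinking successive amplitudes
#' by `depletion_factor` per pulse. A low-K+ control injection produces only a
#' minor disturbance, never a spike.
#'
#' Amplitude defaults are fixtures placed near the platform's reported
#' chemical-stimulation mean (74.4 nA); one base amplitude is drawn per train
#' (truncated normal, lower bound 20 % of the mean) and depletion is applied
#' deterministically within the train.
#'
#' @param baseline Baseline current, nA.
#' @param spike_amp_mean,spike_amp_sd Spike amplitude distribution, nA.
#' @param rise_tau,decay_tau Spike time constants, s (`decay_tau > rise_tau`).
#' @param depletion_factor Per-pulse amplitude factor within a train, in
#'   (0, 1].
#' @param stim_latency Delay from stimulus onset to spike onset, s.
#' @param noise_sd Additive Gaussian noise, nA RMS.
#' @param train_gap Maximum gap (s) between same-kind stimuli that still
#'   counts as one train (default 15).
#' @return An object of class `exocytosis_spec`.
#' @export
exocytosis_spec <- function(baseline = 0, spike_amp_mean = 74.4,
                            spike_amp_sd = 5, rise_tau = 0.2,
                            decay_tau = 1.5, depletion_factor = 0.8,
                            stim_latency = 0.2, noise_sd = 1,
                            train_gap = 15) {
  if (spike_amp_mean < 0 || spike_amp_sd < 0)
    stop_invalid_spec("amplitudes must be >= 0")
  if (!(decay_tau > rise_tau && rise_tau > 0))
    stop_invalid_spec("need decay_tau > rise_tau > 0")
  if (depletion_factor <= 0 || depletion_factor > 1)
    stop_invalid_spec("depletion_factor must lie in (0, 1]")
  if (stim_latency < 0 || noise_sd < 0)
    stop_invalid_spec("stim_latency and noise_sd must be >= 0")
  structure(list(baseline = baseline, spike_amp_mean = spike_amp_mean,
                 spike_amp_sd = spike_amp_sd, rise_tau = rise_tau,
                 decay_tau = decay_tau, depletion_factor = depletion_factor,
                 stim_latency = stim_latency, noise_sd = noise_sd,
                 train_gap = train_gap),
            class = "exocytosis_spec")
}

#' Stimulation protocol
#'
#' @param times Event onset times, s (non-negative, sorted).
#' @param kinds Event kinds: `"high_K"`, `"low_K_control"` or `"light_pulse"`.
#' @param durations Event durations, s.
#' @return An object of class `stimulus_protocol` (data frame of events).
#' @examples
#' # the chemical triple-injection protocol with a low-K+ control at 60 s
#' chemical_protocol()
#' @export
stimulus_protocol <- function(times, kinds, durations = 0.15) {
  if (length(times) == 0L) {
    ev <- data.frame(time = numeric(0), kind = character(0),
                     duration = numeric(0))
    return(structure(list(events = ev), class = "stimulus_protocol"))
  }
  kinds <- match.arg(kinds, c("high_K", "low_K_control", "light_pulse"),
                     several.ok = TRUE)
  if (length(kinds) == 1L) kinds <- rep(kinds, length(times))
  durations <- rep_len(durations, length(times))
  if (any(times < 0)) stop_invalid_spec("event times must be >= 0")
  if (is.unsorted(times)) stop_invalid_spec("event times must be sorted")
  ev <- data.frame(time = times, kind = kinds, duration = durations,
                   stringsAsFactors = FALSE)
  structure(list(events = ev), class = "stimulus_protocol")
}

#' Canonical stimulation protocols
#'
#' `chemical_protocol()`: high-K+ depolarizations at 115, 175 and 235 s with a
#' low-K+ control injection at 60 s. `light_train_protocol()`: a train of
#' `n_pulses` 150 ms light pulses starting at `start`, `period` apart.
#'
#' @param n_pulses Number of light pulses.
#' @param start Train start time, s.
#' @param period Pulse period, s.
#' @return A [stimulus_protocol()].
#' @export
chemical_protocol <- function() {
  stimulus_protocol(c(60, 115, 175, 235),
                    c("low_K_control", "high_K", "high_K", "high_K"),
                    durations = 1)
}

#' @rdname chemical_protocol
#' @export
light_train_protocol <- function(n_pulses = 5, start = 20, period = 10) {
  if (n_pulses == 0) return(stimulus_protocol(numeric(0), character(0)))
  stimulus_protocol(start + period * (seq_len(n_pulses) - 1),
                    rep("light_pulse", n_pulses), durations = 0.15)
}

# Unit-peak difference-of-exponentials spike shape on a time grid (s since
# onset).
spike_shape <- function(dt, rise_tau, decay_tau) {
  raw <- pmax(0, exp(-dt / decay_tau) - exp(-dt / rise_tau))
  raw[dt < 0] <- 0
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  raw / peak
}

#' Simulate an amperometric exocytosis trace
#'
#' Baseline plus one composite spike per stimulating event (`high_K` or
#' `light_pulse`). Consecutive same-kind stimuli closer than
#' `spec$train_gap` form a train: the train's base amplitude is drawn once
#' (truncated normal) and the k-th pulse is scaled by
#' `depletion_factor^(k-1)`. A `low_K_control` event adds only a small, brief
#' disturbance (1 % of the mean amplitude, fast time constants). Additive
#' Gaussian noise is seeded and reproducible. Events spaced closer than
#' `rise_tau` attach an `overlap_warning` attribute.
#'
#' @param spec An [exocytosis_spec()].
#' @param protocol A [stimulus_protocol()]; `duration` must cover all events.
#' @param duration Trace duration, s.
#' @param sample_rate Hz (default 100, the amperometry sampling rate).
#' @param seed Integer seed.
#' @return A [sampled_trace()] in nA with attribute `ground_truth`: data frame
#'   of stimulating events (time, onset, programmed amplitude, train index).
#' @export
simulate_exocytosis_trace <- function(spec, protocol, duration,
                                      sample_rate = 100, seed = 1L) {
  if (!inherits(spec, "exocytosis_spec"))
    stop_invalid_spec("spec must be an exocytosis_spec")
  if (!inherits(protocol, "stimulus_protocol"))
    stop_invalid_spec("protocol must be a stimulus_protocol")
  ev <- protocol$events
  if (nrow(ev) && max(ev$time) > duration)
    stop_invalid_spec("duration must cover all protocol events")
  set.seed(seed)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  v <- rep(spec$baseline, n)

  stim <- ev[ev$kind %in% c("high_K", "light_pulse"), , drop = FALSE]
  gt <- NULL
  if (nrow(stim)) {
    # split stimulating events into trains of consecutive same-kind events
    gap_break <- c(TRUE, diff(stim$time) > spec$train_gap |
                     stim$kind[-1] != stim$kind[-nrow(stim)])
    train_id <- cumsum(gap_break)
    pulse_k <- stats::ave(seq_len(nrow(stim)), train_id, FUN = seq_along)
    base_amp <- vapply(seq_len(max(train_id)), function(id) {
      a <- stats::rnorm(1, spec$spike_amp_mean, spec$spike_amp_sd)
      max(a, 0.2 * spec$spike_amp_mean)
    }, numeric(1))
    amp <- base_amp[train_id] * spec$depletion_factor^(pulse_k - 1)
    onset <- stim$time + spec$stim_latency
    for (i in seq_len(nrow(stim)))
      v <- v + amp[i] * spike_shape(t - onset[i], spec$rise_tau, spec$decay_tau)
    gt <- data.frame(time = stim$time, onset = onset, kind = stim$kind,
                     amplitude = amp, train = train_id, pulse = pulse_k)
  }
  ctrl <- ev[ev$kind == "low_K_control", , drop = FALSE]
  for (i in seq_len(nrow(ctrl))) {
    # minor injection disturbance (1% of the mean spike), no release
    v <- v + 0.01 * spec$spike_amp_mean *
      spike_shape(t - ctrl$time[i], 0.05, 0.3)
  }
  if (spec$noise_sd > 0) v <- v + stats::rnorm(n, 0, spec$noise_sd)
  out <- sampled_trace(v, sample_rate, unit = "nA")
  attr(out, "ground_truth") <- gt
  if (nrow(stim) > 1 && any(diff(stim$time) < spec$rise_tau))
    attr(out, "overlap_warning") <-
      "stimulating events closer than rise_tau; spikes may not resolve"
  out
}

#' Transimpedance-amplifier configuration
#'
#' @param feedback_r Feedback resistor, Ohm (10 kOhm for CV, 10 MOhm for
#'   amperometry in the modelled platform).
#' @param v_sat Output saturation, volts.
#' @param resolution_floor Current sensitivity floor, A (default 20 pA).
#' @return An object of class `tia_config`.
#' @export
tia_config <- function(feedback_r = 1e4, v_sat = 1.5,
                       resolution_floor = 20e-12) {
  if (feedback_r <= 0) stop_invalid_spec("feedback_r must be > 0")
  structure(list(feedback_r = feedback_r, v_sat = v_sat,
                 resolution_floor = resolution_floor),
            class = "tia_config")
}

#' Convert a current trace through the TIA
#'
#' `v = -feedback_r * i`, clipped at `+/- v_sat`. Samples whose current
#' magnitude falls below the sensitivity floor are reported but flagged.
#'
#' @param current A [sampled_trace()] in A, uA or nA.
#' @param cfg A [tia_config()].
#' @return A [sampled_trace()] in volts with attributes `saturated` (logical:
#'   any sample clipped) and `below_sensitivity` (logical vector per sample).
#' @examples
#' tr <- sampled_trace(rep(10, 5), 100, unit = "nA")   # 10 nA
#' tia_convert(tr, tia_config(feedback_r = 1e7))$values  # -0.1 V
#' @export
tia_convert <- function(current, cfg = tia_config()) {
  if (!inherits(current, "sampled_trace"))
    stop_invalid_spec("current must be a sampled_trace")
  scale <- switch(current$unit, A = 1, uA = 1e-6, nA = 1e-9,
                  stop_invalid_spec("current unit must be A, uA or nA"))
  i_amp <- current$values * scale
  v_raw <- -cfg$feedback_r * i_amp
  v <- pmin(pmax(v_raw, -cfg$v_sat), cfg$v_sat)
  out <- sampled_trace(v, current$sample_rate, t0 = current$t0, unit = "V")
  attr(out, "saturated") <- any(abs(v_raw) > cfg$v_sat)
  attr(out, "below_sensitivity") <- abs(i_amp) < cfg$resolution_floor
  out
}
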