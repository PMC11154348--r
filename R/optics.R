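# Optical stimulation model: the PWM-duty -> laser-diode current mapping of
# the constant-current driver (lower duty means higher current), a
# linear-above-threshold power curve capped by the platform's delivery limit,
# beam-propagation irradiance, and channelrhodopsin-2 threshold checks.

#' Laser-diode model
#'
#' Defaults describe a 450 nm diode driven between 5 and 40 mA that emits
#' about 25 mW at full current, on a platform capped at 20 mW delivered
#' power. Threshold current and slope efficiency are fixtures fitted to that
#' single operating point.
#'
#' @param i_min,i_max Driver current range, mA (0 < i_min < i_max).
#' @param i_threshold Lasing threshold current, mA.
#' @param slope_eff Slope efficiency above threshold, mW/mA.
#' @param p_max_platform Platform power cap, mW.
#' @param wavelength Emission wavelength, nm.
#' @return An object of class `laser_diode`.
#' @export
laser_diode <- function(i_min = 5, i_max = 40, i_threshold = 20,
                        slope_eff = 1.25, p_max_platform = 20,
                        wavelength = 450) {
  if (!(i_min > 0 && i_max > i_min))
    stop_invalid_spec("need 0 < i_min < i_max")
  uncapped_max <- slope_eff * (i_max - i_threshold)
  if (p_max_platform > uncapped_max)
    stop_invalid_spec("p_max_platform must not exceed the diode's maximum power")
  structure(list(i_min = i_min, i_max = i_max, i_threshold = i_threshold,
                 slope_eff = slope_eff, p_max_platform = p_max_platform,
                 wavelength = wavelength),
            class = "laser_diode")
}

#' PWM duty cycle to laser-diode current
#'
#' The driver's current-set pin is fed a low-pass-filtered PWM signal; because
#' of the driver's internal structure, decreasing the duty cycle increases the
#' diode current. Modelled as the strictly decreasing affine map with
#' `current(1) = i_min` and `current(0) = i_max`, clamped to the driver range.
#'
#' @param duty Duty-cycle fraction in `[0, 1]`.
#' @param ld A [laser_diode()].
#' @return Current in mA.
#' @examples
#' duty_to_current(0)  # 40 mA
#' duty_to_current(1)  # 5 mA
#' @export
duty_to_current <- function(duty, ld = laser_diode()) {
  if (any(duty < 0 | duty > 1)) stop_range("duty must lie in [0, 1]")
  i <- ld$i_max + duty * (ld$i_min - ld$i_max)
  pmin(pmax(i, ld$i_min), ld$i_max)
}

#' Laser-diode current to optical power
#'
#' Zero below the lasing threshold, linear with `slope_eff` above it, capped
#' at the platform's maximum deliverable power.
#'
#' @param i Drive current, mA (>= 0).
#' @param ld A [laser_diode()].
#' @return Optical power, mW.
#' @examples
#' current_to_power(40)  # 20 mW after the platform cap (25 mW uncapped)
#' @export
current_to_power <- function(i, ld = laser_diode()) {
  if (any(i < 0)) stop_invalid_spec("current must be >= 0")
  p <- pmax(0, ld$slope_eff * (i - ld$i_threshold))
  pmin(p, ld$p_max_platform)
}

#' Beam geometry for irradiance calculations
#'
#' @param aperture_diameter Beam diameter at the aperture, mm (> 0).
#' @param divergence_full_angle Full divergence angle, rad (>= 0).
#' @param distance Propagation distance to the target plane, mm (>= 0).
#' @param transmission Optical transmission (ND filters etc.) in `[0, 1]`.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(aperture_diameter, divergence_full_angle = 0,
                          distance = 0, transmission = 1) {
  if (aperture_diameter <= 0)
    stop_invalid_spec("aperture_diameter must be > 0")
  if (divergence_full_angle < 0 || distance < 0)
    stop_invalid_spec("divergence and distance must be >= 0")
  if (transmission < 0 || transmission > 1)
    stop_invalid_spec("transmission must lie in [0, 1]")
  structure(list(aperture_diameter = aperture_diameter,
                 divergence_full_angle = divergence_full_angle,
                 distance = distance, transmission = transmission),
            class = "beam_geometry")
}

#' Irradiance at the target plane
#'
#' The spot diameter grows as
#' `d(z) = aperture_diameter + 2 z tan(divergence_full_angle / 2)` (the
#' divergence is interpreted as a full angle), and the irradiance is the
#' transmitted power spread uniformly over the spot:
#' `E = power * transmission / (pi (d/2)^2)`.
#'
#' @param beam A [beam_geometry()].
#' @param power Beam power at the aperture, mW (>= 0).
#' @return Irradiance, mW/mm^2.
#' @examples
#' # external stimulation laser: 5 mm aperture, 0.5 mrad, 50 cm, 50 % ND
#' irradiance_at(beam_geometry(5, 0.5e-3, 500, 0.5), 40)
#' @export
irradiance_at <- function(beam, power) {
  if (power < 0) stop_invalid_spec("power must be >= 0")
  d <- beam$aperture_diameter +
    2 * beam$distance * tan(beam$divergence_full_angle / 2)
  power * beam$transmission / (pi * (d / 2)^2)
}

#' Optical power required to reach a threshold irradiance
#'
#' @param threshold Threshold irradiance, mW/mm^2 (>= 0).
#' @param area Illuminated area, mm^2 (>= 0).
#' @return Required power at the target surface, mW (`threshold * area`).
#' @examples
#' required_power(1, 12.56)  # 12.56 mW over the culture-well electrode
#' @export
required_power <- function(threshold, area) {
  if (threshold < 0 || area < 0)
    stop_invalid_spec("threshold and area must be >= 0")
  threshold * area
}

#' Channelrhodopsin-2 activation check
#'
#' Literature threshold bands: about 0.3 to 1 mW/mm^2 for in vitro
#' preparations and 1 to 5 mW/mm^2 for brain tissue. Below the band the
#' irradiance is insufficient, inside it marginal (activation depends on
#' expression level), above it sufficient.
#'
#' @param irradiance mW/mm^2 (>= 0).
#' @param context `"in_vitro"` or `"brain_tissue"`.
#' @return One of `"insufficient"`, `"marginal"`, `"sufficient"`.
#' @examples
#' chr2_check(0.5, "in_vitro")   # marginal
#' chr2_check(6, "brain_tissue") # sufficient
#' @export
chr2_check <- function(irradiance, context = c("in_vitro", "brain_tissue")) {
  if (irradiance < 0) stop_invalid_spec("irradiance must be >= 0")
  if (length(context) != 1 || !context %in% c("in_vitro", "brain_tissue"))
    stop_invalid_spec("context must be 'in_vitro' or 'brain_tissue'")
  bounds <- switch(context, in_vitro = c(0.3, 1), brain_tissue = c(1, 5))
  if (irradiance < bounds[1]) "insufficient"
  else if (irradiance <= bounds[2]) "marginal"
  else "sufficient"
}

#' Stimulation report: envelope, power, irradiance, ChR2 verdict
#'
#' Convenience wrapper chaining the driver, diode and beam models for a pulse
#' train.
#'
#' @param train A [pulse_train()].
#' @param beam A [beam_geometry()].
#' @param ld A [laser_diode()].
#' @param sample_rate Envelope sampling rate, Hz.
#' @param context ChR2 context for the verdict.
#' @return List with `envelope` ([sampled_trace()]), `current_ma`, `power_mw`,
#'   `irradiance_mw_mm2`, `verdict`.
#' @export
stimulation_report <- function(train, beam, ld = laser_diode(),
                               sample_rate = 1000,
                               context = "in_vitro") {
  current <- duty_to_current(train$power_setting, ld)
  power <- current_to_power(current, ld)
  irr <- irradiance_at(beam, power)
  list(envelope = build_pulse_train(train, sample_rate),
       current_ma = current, power_mw = power,
       irradiance_mw_mm2 = irr,
       verdict = chr2_check(irr, context))
}
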