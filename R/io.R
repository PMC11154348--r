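# CSV and configuration interfaces. Trace files use the dialect
# `time_s,value,<unit>`: the header's third token carries the unit, data rows
# carry time and value. Spectra use `frequency_hz,zmag_ohm,phase_deg`.
# Numbers are written with 15 significant digits so a write/read round trip is
# lossless to 12 digits.

fmt_num <- function(x) sprintf("%.15g", x)

#' Write / read a sampled trace as CSV
#'
#' @param trace A [sampled_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   [sampled_trace()].
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "sampled_trace"))
    stop_invalid_spec("trace must be a sampled_trace")
  t <- trace_times(trace)
  lines <- c(paste("time_s", "value", trace$unit, sep = ","),
             paste(fmt_num(t), fmt_num(trace$values), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop_format("empty file: no header")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) != 3 || header[1] != "time_s" || header[2] != "value")
    stop_format("malformed trace header; expected 'time_s,value,<unit>'")
  unit <- header[3]
  if (!unit %in% c("mV", "uA", "nA", "V", "dimensionless"))
    stop_format(sprintf("unknown trace unit '%s'", unit))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) return(sampled_trace(numeric(0), 1, unit = unit))
  d <- utils::read.csv(text = body, header = FALSE,
                       colClasses = "numeric")
  if (ncol(d) != 2) stop_format("trace rows must have two fields")
  t <- d[[1]]; v <- d[[2]]
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
      stop_format("non-uniform time step in trace file")
    rate <- 1 / stats::median(dt)
  } else rate <- 1
  sampled_trace(v, rate, t0 = t[1], unit = unit)
}

#' Write / read an impedance spectrum as CSV
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path File path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns an [impedance_spectrum()]. Frequencies must be strictly
#'   ascending, magnitudes positive, phases in (-180, 180]; violations raise
#'   a format error.
#' @export
write_spectrum <- function(spectrum, path) {
  if (!inherits(spectrum, "impedance_spectrum"))
    stop_invalid_spec("spectrum must be an impedance_spectrum")
  lines <- c("frequency_hz,zmag_ohm,phase_deg",
             paste(fmt_num(spectrum$frequencies), fmt_num(spectrum$z_mag),
                   fmt_num(spectrum$phase_deg), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines) || lines[1] != "frequency_hz,zmag_ohm,phase_deg")
    stop_format("malformed spectrum header")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body))
    return(impedance_spectrum(numeric(0), numeric(0), numeric(0)))
  d <- utils::read.csv(text = body, header = FALSE, colClasses = "numeric")
  if (ncol(d) != 3) stop_format("spectrum rows must have three fields")
  impedance_spectrum(d[[1]], d[[2]], d[[3]])
}

#' Write a relative-impedance report
#'
#' Per-frequency relative impedance plus a one-line band-mean footer record.
#'
#' @param rel A [relative_impedance()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_relative_report <- function(rel, path) {
  lines <- c("frequency_hz,relative_impedance_pct",
             paste(fmt_num(rel$frequencies), fmt_num(rel$per_frequency),
                   sep = ","),
             paste("band_mean_pct", fmt_num(rel$band_mean), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

config_schemas <- list(
  randles_cell = c("r_s", "r_ct", "q_dl", "alpha", "coverage"),
  demod = c("adc_bits", "adc_full_scale", "min_periods",
            "samples_per_period", "r_ref"),
  redox_couple = c("e0", "n_electrons", "diffusion_coeff", "bulk_conc",
                   "reversible"),
  electrode = c("area", "material"),
  cv_waveform = c("v_start", "v_vertex_low", "v_vertex_high", "scan_rate",
                  "n_cycles", "sample_rate"),
  pulse_train = c("n_pulses", "pulse_width", "pulse_period", "power_setting",
                  "total_duration"),
  beam = c("aperture_diameter", "divergence_full_angle", "distance",
           "transmission"),
  exocytosis = c("baseline", "spike_amp_mean", "spike_amp_sd", "rise_tau",
                 "decay_tau", "depletion_factor", "stim_latency", "noise_sd",
                 "train_gap"),
  protocol = c("times", "kinds", "durations"),
  tia = c("feedback_r", "v_sat", "resolution_floor"),
  laser_diode = c("i_min", "i_max", "i_threshold", "slope_eff",
                  "p_max_platform", "wavelength")
)

config_builders <- list(
  randles_cell = function(a) do.call(randles_cell, a),
  demod = function(a) do.call(demod_config, a),
  redox_couple = function(a) do.call(redox_couple, a),
  electrode = function(a) do.call(electrode_spec, a),
  cv_waveform = function(a) do.call(cv_waveform_spec, a),
  pulse_train = function(a) do.call(pulse_train, a),
  beam = function(a) do.call(beam_geometry, a),
  exocytosis = function(a) do.call(exocytosis_spec, a),
  protocol = function(a) do.call(stimulus_protocol, a),
  tia = function(a) do.call(tia_config, a),
  laser_diode = function(a) do.call(laser_diode, a)
)

#' Load and validate a structured configuration
#'
#' Reads a YAML file whose top-level keys name configuration blocks
#' (`randles_cell`, `demod`, `redox_couple`, `electrode`, `cv_waveform`,
#' `pulse_train`, `beam`, `exocytosis`, `protocol`, `tia`, `laser_diode`).
#' Every block is passed through the corresponding constructor, so all type
#' invariants are enforced at load time and defaults are injected for omitted
#' fields. Unknown blocks or fields raise an error naming the offender;
#' duplicate keys are rejected by the YAML parser.
#'
#' @param path Path to a YAML file.
#' @return Named list of validated objects, one per block, with attribute
#'   `defaults_injected` listing defaulted fields.
#' @export
load_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop_format(paste("config parse error:",
                                      conditionMessage(e))))
  if (!is.list(raw)) stop_format("config must be a mapping of blocks")
  unknown <- setdiff(names(raw), names(config_schemas))
  if (length(unknown))
    stop_format(paste("unknown config block(s):",
                      paste(unknown, collapse = ", ")))
  injected <- list()
  out <- lapply(names(raw), function(block) {
    fields <- raw[[block]]
    if (is.null(fields)) fields <- list()
    bad <- setdiff(names(fields), config_schemas[[block]])
    if (length(bad))
      stop_format(sprintf("unknown field(s) in block '%s': %s",
                          block, paste(bad, collapse = ", ")))
    injected[[block]] <<- setdiff(config_schemas[[block]], names(fields))
    tryCatch(config_builders[[block]](fields),
             headstage_error = function(e)
               hs_stop(sprintf("config block '%s': %s", block,
                               conditionMessage(e)),
                       class(e)[1]))
  })
  names(out) <- names(raw)
  attr(out, "defaults_injected") <- injected
  out
}

#' Write a run manifest
#'
#' Records the command, an MD5 digest of the configuration file, the seed, a
#' timestamp and the produced outputs, so a stochastic run can be reproduced
#' byte-identically from (config, seed).
#'
#' @param path Manifest destination (JSON).
#' @param command Command or function name.
#' @param config_path Configuration file the run used (`NA` if none).
#' @param seed Integer seed.
#' @param outputs Character vector of output files.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config_path = NA, seed = NA,
                           outputs = character(0)) {
  manifest <- list(
    command = command,
    config = if (is.na(config_path)) NA else config_path,
    config_md5 = if (is.na(config_path)) NA
                 else unname(tools::md5sum(config_path)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
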