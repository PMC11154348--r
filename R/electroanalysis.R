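# Analysis of measured or simulated traces: Savitzky-Golay smoothing, CV peak
# extraction and peak-to-peak separation, amperometric spike detection with
# robust thresholding, and the fast-scan CV throughput arithmetic.

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing of a uniformly sampled trace;
#' boundary samples are handled by the asymmetric polynomial fits of the
#' filter matrix, so an exact polynomial of degree `<= polyorder` passes
#' through unchanged everywhere, edges included.
#'
#' @param trace A [sampled_trace()].
#' @param window Odd window length in samples (default 11).
#' @param polyorder Polynomial order `< window` (default 3).
#' @return The smoothed [sampled_trace()].
#' @export
savgol_smooth <- function(trace, window = 11, polyorder = 3) {
  if (!inherits(trace, "sampled_trace"))
    stop_invalid_spec("trace must be a sampled_trace")
  if (window %% 2 == 0) stop_invalid_spec("window must be odd")
  if (polyorder >= window)
    stop_invalid_spec("polyorder must be smaller than window")
  if (length(trace$values) < window)
    stop_insufficient("trace shorter than the smoothing window")
  sm <- signal::sgolayfilt(trace$values, p = polyorder, n = window)
  sampled_trace(sm, trace$sample_rate, t0 = trace$t0, unit = trace$unit)
}

#' Extract anodic and cathodic peaks from a cyclic voltammogram
#'
#' Splits the cycle at the vertices (by sweep direction): the anodic peak is
#' the current maximum on the positive-going half, the cathodic peak the
#' minimum on the negative-going half; potentials are reported at the extremum
#' sample. An extremum indistinguishable from the segment endpoints (monotone
#' current) raises a no-peak error.
#'
#' @param cv A [cv_trace()] containing at least one full forward and reverse
#'   sweep.
#' @return An object of class `peak_pair`: list with `anodic_potential`,
#'   `anodic_current`, `cathodic_potential`, `cathodic_current` (mV, uA).
#' @export
find_cv_peaks <- function(cv) {
  if (!inherits(cv, "cv_trace")) stop_invalid_spec("cv must be a cv_trace")
  dv <- diff(cv$potential)
  up <- which(dv > 0)
  down <- which(dv < 0)
  if (!length(up) || !length(down))
    stop_invalid_spec("cv must contain both a forward and a reverse sweep")
  interior_extremum <- function(idx, minimize = FALSE) {
    cur <- cv$current[idx]
    j <- if (minimize) which.min(cur) else which.max(cur)
    if (j == 1L || j == length(idx))
      stop_no_peak("no extremum distinguishable from the sweep endpoints")
    idx[j]
  }
  ia <- interior_extremum(up)
  ic <- interior_extremum(down, minimize = TRUE)
  structure(list(anodic_potential = cv$potential[ia],
                 anodic_current = cv$current[ia],
                 cathodic_potential = cv$potential[ic],
                 cathodic_current = cv$current[ic]),
            class = "peak_pair")
}

#' @export
print.peak_pair <- function(x, ...) {
  cat(sprintf(
    "<peak_pair> anodic %.4g uA @ %.4g mV; cathodic %.4g uA @ %.4g mV; dEp = %.4g mV\n",
    x$anodic_current, x$anodic_potential,
    x$cathodic_current, x$cathodic_potential, peak_separation(x)))
  invisible(x)
}

#' Peak-to-peak separation
#'
#' Absolute difference of the anodic and cathodic peak potentials. The ideal
#' reversible value at 25 C is 57/n mV for an n-electron transfer; measured
#' separations exceed it when uncompensated resistance distorts the sweep.
#'
#' @param pair A [find_cv_peaks()] result, or any list with
#'   `anodic_potential` and `cathodic_potential` in mV.
#' @return Separation in mV.
#' @examples
#' peak_separation(list(anodic_potential = 85, cathodic_potential = -85))
#' @export
peak_separation <- function(pair) {
  abs(pair$anodic_potential - pair$cathodic_potential)
}

#' Detect amperometric spikes
#'
#' Baseline = rolling median over `baseline_window`; threshold = `k_threshold`
#' times the robust SD (1.4826 x MAD) of the baseline-subtracted signal.
#' Each contiguous region above threshold contributes one candidate (its
#' maximum); candidates must be separated by at least `min_separation` (the
#' taller peak wins a conflict) and must rise by at least the threshold above
#' the valley separating them from any taller accepted peak (topographic
#' prominence), which keeps noise ripples riding on a spike's decay tail from
#' being counted as events. Amplitude is peak minus local baseline; width is
#' the full width at half maximum of the baseline-subtracted spike.
#'
#' @param trace A [sampled_trace()] sampled at >= 10 Hz.
#' @param baseline_window Rolling-median window, s (default 10).
#' @param k_threshold Threshold multiplier (default 5).
#' @param min_separation Minimum event spacing, s (default 1).
#' @return List with `events` (data frame: `t_peak`, `amplitude`,
#'   `width_half_max`) and `stats` (list: `n_events`, `mean_amp`, `sd_amp`;
#'   `sd_amp` is `NA` for fewer than two events).
#' @export
detect_spikes <- function(trace, baseline_window = 10, k_threshold = 5,
                          min_separation = 1) {
  if (!inherits(trace, "sampled_trace"))
    stop_invalid_spec("trace must be a sampled_trace")
  fs <- trace$sample_rate
  if (fs < 10) stop_invalid_spec("trace must be sampled at >= 10 Hz")
  x <- trace$values
  w <- round(baseline_window * fs)
  if (length(x) < w) stop_insufficient("trace shorter than baseline_window")
  if (w %% 2 == 0) w <- w + 1
  baseline <- stats::runmed(x, w, endrule = "median")
  d <- x - baseline
  sigma <- 1.4826 * stats::median(abs(d - stats::median(d)))
  thr <- k_threshold * sigma
  n <- length(d)
  # one candidate per contiguous above-threshold region: its maximum
  above <- d > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- vapply(which(runs$values), function(r)
    as.integer(starts[r] - 1L + which.max(d[starts[r]:ends[r]])), integer(1))
  # tallest first: enforce min_separation and topographic prominence
  cand <- cand[order(d[cand], decreasing = TRUE)]
  min_gap <- round(min_separation * fs)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && any(abs(i - keep) < min_gap)) next
    prominent <- TRUE
    for (side in c(-1, 1)) {
      nb <- keep[if (side < 0) keep < i else keep > i]
      if (!length(nb)) next
      j <- nb[which.min(abs(nb - i))]   # nearest accepted (taller) peak
      valley <- min(d[min(i, j):max(i, j)])
      if (d[i] - valley < thr) { prominent <- FALSE; break }
    }
    if (prominent) keep <- c(keep, i)
  }
  keep <- sort(keep)
  t <- trace_times(trace)
  width <- vapply(keep, function(i) {
    half <- d[i] / 2
    l <- i; while (l > 1 && d[l] > half) l <- l - 1
    r <- i; while (r < n && d[r] > half) r <- r + 1
    (r - l) / fs
  }, numeric(1))
  events <- data.frame(t_peak = t[keep], amplitude = d[keep],
                       width_half_max = width)
  stats <- list(n_events = nrow(events),
                mean_amp = if (nrow(events)) mean(events$amplitude) else NA_real_,
                sd_amp = if (nrow(events) > 1) stats::sd(events$amplitude) else NA_real_)
  list(events = events, stats = stats)
}

#' Fast-scan CV throughput
#'
#' How many voltammograms a fast-scan protocol generates: at the typical 10 Hz
#' repetition rate, one hour yields 36,000 CVs.
#'
#' @param rep_rate Scan repetition rate, Hz (>= 0).
#' @param duration Duration, hours.
#' @return Scan count, `floor(rep_rate * 3600 * duration)`.
#' @examples
#' fscv_throughput(10, 1)  # 36000
#' @export
fscv_throughput <- function(rep_rate, duration) {
  if (rep_rate < 0) stop_invalid_spec("rep_rate must be >= 0")
  floor(rep_rate * 3600 * duration)
}
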