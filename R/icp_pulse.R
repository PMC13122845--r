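# Baseline ICP pulse analysis: the dP_CC side of physiological compliance.
#
# Chain: select a baseline window shortly before infusion start -> estimate
# the cardiac fundamental from the spectrum -> FFT band-pass to strip
# respiration and high-frequency noise -> peak detection to segment beats ->
# ensemble-average onto a normalized 32-point cycle -> amplitude (max - min)
# of the average pulse is dP_CC.

#' Select the baseline ICP segment used for pulse analysis
#'
#' Takes the `window_s`-long stretch of the annotated baseline ending
#' `gap_s` before infusion start: late enough that the patient has settled,
#' with a guard gap so no infusion-related rise leaks in. If the annotated
#' baseline is shorter than requested the whole baseline is used with a
#' warning; below 10 s of baseline pulse analysis is refused.
#'
#' @param rec An [icp_recording].
#' @param window_s Segment length, s.
#' @param gap_s Guard gap before infusion start, s.
#' @return An [icp_segment] with origin `"baseline"`.
#' @export
select_baseline <- function(rec, window_s = 30, gap_s = 10) {
  stopifnot(inherits(rec, "icp_recording"))
  a <- rec$annotations
  fs <- rec$sampling_hz
  t_end <- min(a$baseline_end_s, a$infusion_start_s - gap_s)
  t_start <- t_end - window_s
  if (t_start < a$baseline_start_s) {
    t_start <- a$baseline_start_s
    t_end <- a$baseline_end_s
    if (t_end - t_start < 10) {
      stopf("baseline too short for pulse analysis: %.1f s (need >= 10 s)",
            t_end - t_start)
    }
    warnf("baseline shorter than %g s window; using full %.1f s baseline",
          window_s, t_end - t_start)
  }
  idx <- time_window_idx(t_start, t_end, fs, length(rec$icp_mmHg))
  icp_segment(rec$icp_mmHg[idx], fs, origin = "baseline")
}

#' Estimate the cardiac fundamental frequency of an ICP segment
#'
#' Largest spectral magnitude (after mean removal) inside the plausible
#' cardiac band, by default 0.8-2.5 Hz (48-150 BPM), followed by a
#' subharmonic check: if the spectrum carries substantial power near half
#' the winning frequency — still above the respiratory band (> 0.55 Hz) —
#' the winner was a harmonic of a slow heart and the subharmonic is taken
#' instead. Errors if no bin stands clearly above the in-band noise floor.
#'
#' @param seg An [icp_segment] of at least 10 s.
#' @param band Search band `c(lo, hi)` in Hz.
#' @param subharmonic_min_hz Lowest admissible fundamental for the
#'   subharmonic check (must exceed the respiratory band).
#' @param min_peak_ratio Required ratio of the winning magnitude to the
#'   in-band median magnitude; pure white noise stays near 2.5, a real
#'   cardiac line well above.
#' @return Cardiac frequency estimate, Hz.
#' @export
estimate_cardiac_frequency <- function(seg, band = c(0.8, 2.5),
                                       subharmonic_min_hz = 0.55,
                                       min_peak_ratio = 4) {
  stopifnot(inherits(seg, "icp_segment"))
  x <- seg$values_mmHg
  fs <- seg$sampling_hz
  n <- length(x)
  if (n / fs < 10) stopf("segment too short to estimate cardiac rate (< 10 s)")
  mag <- Mod(stats::fft(x - mean(x)))
  freq <- (seq_len(n) - 1L) / n * fs
  half <- freq <= fs / 2
  inband <- which(half & freq >= band[1] & freq <= band[2])
  if (!length(inband)) stopf("cardiac search band [%g, %g] Hz holds no bins",
                             band[1], band[2])
  m <- mag[inband]
  floor_mag <- stats::median(m)
  scale <- max(mag)   # whole-spectrum scale guards against all-zero input
  if (max(m) <= 1e-12 * max(scale, 1) ||
      (floor_mag > 0 && max(m) < min_peak_ratio * floor_mag)) {
    stopf("no cardiac spectral peak above the noise floor in [%g, %g] Hz",
          band[1], band[2])
  }
  f_hat <- freq[inband[which.max(m)]]
  peak_mag <- max(m)
  # Subharmonic check: a fundamental just below the search band leaves its
  # 2nd harmonic as the in-band winner.
  f_sub <- f_hat / 2
  if (f_sub >= subharmonic_min_hz && f_sub < band[1]) {
    df <- fs / n
    near <- which(half & abs(freq - f_sub) <= 1.5 * df)
    if (length(near) && max(mag[near]) > 0.5 * peak_mag) {
      f_hat <- freq[near[which.max(mag[near])]]
    }
  }
  f_hat
}

#' FFT band-pass filter for an ICP segment
#'
#' Forward DFT, hard-zeroing of every bin outside the kept band, inverse
#' DFT. The default band `[0.66 * f_c, min(15, 10 * f_c)]` Hz removes the
#' respiratory oscillation (<= 0.5 Hz) and slow drift below the slowest
#' plausible cardiac fundamental while retaining ~10 harmonics of the pulse
#' shape. The DC bin is kept by default so the filtered segment stays at
#' physiologic mean pressure; the pulse amplitude is DC-invariant either way.
#' An optional raised-cosine taper of the band edges is available instead of
#' hard zeroing.
#'
#' @param seg An [icp_segment].
#' @param f_c Cardiac fundamental from [estimate_cardiac_frequency()], Hz.
#' @param keep Kept band `c(lo, hi)` in Hz; `NULL` for the default above.
#' @param keep_dc Retain the DC bin.
#' @param taper_hz Width of a raised-cosine transition at each band edge; 0
#'   (default) gives hard bin zeroing.
#' @return The filtered [icp_segment] (same length, real-valued).
#' @export
fft_bandpass <- function(seg, f_c, keep = NULL, keep_dc = TRUE,
                         taper_hz = 0) {
  stopifnot(inherits(seg, "icp_segment"))
  if (is.null(keep)) keep <- c(0.66 * f_c, min(15, 10 * f_c))
  if (keep[2] <= keep[1]) stopf("empty keep band [%g, %g] Hz",
                                keep[1], keep[2])
  x <- seg$values_mmHg
  n <- length(x)
  fs <- seg$sampling_hz
  freq <- (seq_len(n) - 1L) / n * fs
  fabs <- pmin(freq, fs - freq)        # absolute frequency of each bin
  if (taper_hz > 0) {
    gain <- edge_taper(fabs, keep, taper_hz)
  } else {
    gain <- as.numeric(fabs >= keep[1] & fabs <= keep[2])
  }
  gain[1] <- if (keep_dc) 1 else 0
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  icp_segment(y, fs, origin = seg$origin)
}

#' @keywords internal
#' @noRd
edge_taper <- function(fabs, keep, taper_hz) {
  g <- numeric(length(fabs))
  lo <- keep[1]; hi <- keep[2]
  g[fabs >= lo & fabs <= hi] <- 1
  ramp_in <- fabs > lo - taper_hz & fabs < lo
  g[ramp_in] <- 0.5 * (1 + cos(pi * (lo - fabs[ramp_in]) / taper_hz))
  ramp_out <- fabs > hi & fabs < hi + taper_hz
  g[ramp_out] <- 0.5 * (1 + cos(pi * (fabs[ramp_out] - hi) / taper_hz))
  g
}

#' Segment a filtered ICP trace into individual cardiac pulses
#'
#' Peaks are detected with minimum separation `min_sep_factor / f_c` seconds
#' and topographic prominence at least `prominence_factor` times the segment
#' SD — guards against double-counting P2 sub-peaks taller than P1. Each
#' pulse is the half-open span between consecutive peaks. Pulses whose
#' length deviates more than `length_tol` from the median pulse length
#' (missed or spurious peaks, ectopic-like beats) are discarded with a
#' message.
#'
#' @param seg A filtered [icp_segment].
#' @param f_c Cardiac fundamental, Hz.
#' @param min_sep_factor Minimum peak separation as a fraction of the
#'   cardiac period.
#' @param prominence_factor Prominence threshold as a fraction of the
#'   segment SD.
#' @param length_tol Relative deviation from the median pulse length beyond
#'   which a pulse is discarded.
#' @return List of numeric vectors (one per retained pulse), with attributes
#'   `n_discarded` and `sampling_hz`.
#' @export
segment_pulses <- function(seg, f_c, min_sep_factor = 0.6,
                           prominence_factor = 0.25, length_tol = 0.25) {
  stopifnot(inherits(seg, "icp_segment"))
  x <- seg$values_mmHg
  fs <- seg$sampling_hz
  min_dist <- max(1L, round(min_sep_factor / f_c * fs))
  peaks <- find_peaks(x, min_distance = min_dist,
                      min_prominence = prominence_factor * stats::sd(x))
  if (length(peaks) < 4L) {
    stopf("found %d peak(s); need at least 4 to form 3 pulses",
          length(peaks))
  }
  pulses <- lapply(seq_len(length(peaks) - 1L), function(i) {
    x[peaks[i]:(peaks[i + 1L] - 1L)]
  })
  len <- lengths(pulses)
  med <- stats::median(len)
  ok <- abs(len - med) <= length_tol * med
  if (any(!ok)) {
    message(sprintf(
      "segment_pulses: discarded %d of %d pulse(s) with length > %.0f%% from the median",
      sum(!ok), length(ok), 100 * length_tol))
  }
  pulses <- pulses[ok]
  if (length(pulses) < 3L) {
    stopf("only %d pulse(s) retained after length screening; need >= 3",
          length(pulses))
  }
  attr(pulses, "n_discarded") <- sum(!ok)
  attr(pulses, "sampling_hz") <- fs
  pulses
}

#' Ensemble-average segmented pulses into one representative cycle
#'
#' Each pulse, aligned at its starting peak, is linearly resampled onto a
#' normalized cycle of `n_points` samples and the resampled pulses are
#' averaged pointwise. 32 points mirror the cine PC-MRI reconstruction count
#' so both sides of the compliance ratio live on the same cycle grid.
#'
#' @param pulses Output of [segment_pulses()] (or a list of numeric vectors,
#'   in which case `sampling_hz` must be supplied).
#' @param n_points Samples of the normalized cycle.
#' @param sampling_hz Sampling rate of the raw pulses, Hz; defaults to the
#'   attribute set by [segment_pulses()].
#' @return An object of class `average_pulse` with `values_mmHg`
#'   (`n_points` samples), `period_s` (mean beat duration), `n_beats`,
#'   `delta_p_cc_mmHg`.
#' @export
average_pulse <- function(pulses, n_points = 32L,
                          sampling_hz = attr(pulses, "sampling_hz")) {
  if (length(pulses) < 3L) stopf("need at least 3 pulses to average")
  if (is.null(sampling_hz)) stopf("sampling_hz not supplied")
  len <- lengths(pulses)
  if (any(len < 2L)) stopf("degenerate (near-empty) pulse in input")
  grid <- (seq_len(n_points) - 1L) / n_points
  mat <- vapply(pulses, function(p) {
    pos <- (seq_along(p) - 1L) / length(p)
    stats::approx(pos, p, xout = grid, rule = 2)$y
  }, numeric(n_points))
  avg <- rowMeans(mat)
  structure(
    list(values_mmHg = avg,
         period_s = mean(len) / sampling_hz,
         n_beats = length(pulses),
         delta_p_cc_mmHg = max(avg) - min(avg)),
    class = "average_pulse"
  )
}

#' @export
print.average_pulse <- function(x, ...) {
  cat(sprintf(
    "<average_pulse> %d beats, T = %.3f s (%.0f BPM), dP_CC = %.2f mmHg\n",
    x$n_beats, x$period_s, 60 / x$period_s, x$delta_p_cc_mmHg))
  invisible(x)
}

#' Amplitude of the average ICP pulse (dP_CC)
#'
#' @param pulse An [average_pulse].
#' @return `max - min` of the averaged waveform, mmHg.
#' @export
delta_p_cc <- function(pulse) {
  stopifnot(inherits(pulse, "average_pulse"))
  max(pulse$values_mmHg) - min(pulse$values_mmHg)
}

#' Full baseline pulse chain for one recording
#'
#' Convenience wrapper running [select_baseline()],
#' [estimate_cardiac_frequency()], [fft_bandpass()], [segment_pulses()] and
#' [average_pulse()] with a single configuration list (see
#' [analysis_config()]).
#'
#' @param rec An [icp_recording].
#' @param config An [analysis_config()] list.
#' @return An [average_pulse].
#' @export
baseline_pulse <- function(rec, config = analysis_config()) {
  p <- config$pulse
  seg <- select_baseline(rec, window_s = p$window_s, gap_s = p$gap_s)
  f_c <- estimate_cardiac_frequency(seg, band = p$cardiac_band_hz)
  filt <- fft_bandpass(seg, f_c, keep = p$keep_band_hz, keep_dc = p$keep_dc,
                       taper_hz = p$taper_hz)
  pulses <- segment_pulses(filt, f_c,
                           min_sep_factor = p$min_sep_factor,
                           prominence_factor = p$prominence_factor,
                           length_tol = p$length_tol)
  average_pulse(pulses, n_points = p$n_points)
}
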