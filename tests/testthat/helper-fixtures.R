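# Fixture builders shared across the test files. All fixtures are generated
# in code; ground truth (amplitudes, rates, time constants) is known by
# construction.

# Baseline ICP segment with known cardiac peak-to-peak amplitude, built on
# the package's triphasic pulse template.
make_baseline_segment <- function(duration_s = 30, fs = 100, hr_bpm = 72,
                                  p2p = 3, mean_icp = 12,
                                  resp_amp = 0, resp_freq = 0.25,
                                  noise_sd = 0, jitter = 0) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / hr_bpm
  nb <- ceiling(duration_s / (period * 0.8)) + 2L
  durs <- pmax(period * (1 + jitter * stats::rnorm(nb)), 0.4 * period)
  starts <- c(0, cumsum(durs))
  b <- findInterval(t, starts)
  ph <- (t - starts[b]) / durs[b]
  tmpl <- craniospinal:::pulse_template()
  x <- mean_icp +
    p2p * tmpl[pmin(length(tmpl), floor(ph * length(tmpl)) + 1L)] +
    resp_amp * sin(2 * pi * resp_freq * t) +
    stats::rnorm(n, 0, noise_sd)
  icp_segment(x, fs, origin = "baseline")
}

# Run the pulse chain downstream of baseline selection.
run_pulse_chain <- function(seg) {
  f_c <- estimate_cardiac_frequency(seg)
  filt <- fft_bandpass(seg, f_c)
  pulses <- suppressMessages(segment_pulses(filt, f_c))
  average_pulse(pulses)
}

# Pulse-free infusion recording whose trend rises as a single exponential
# towards a plateau; closed-form ground truth for the plateau detector.
make_exponential_recording <- function(icp_b = 10, dp = 20, tau = 120,
                                       baseline_s = 120, total_s = 1500,
                                       fs = 100, rate = 1.5) {
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- rep(icp_b, n)
  post <- t >= baseline_s
  x[post] <- icp_b + dp * (1 - exp(-(t[post] - baseline_s) / tau))
  icp_recording(x, fs, annotations = list(
    baseline_start_s = 0, baseline_end_s = baseline_s,
    infusion_start_s = baseline_s, infusion_rate_ml_per_min = rate,
    recording_end_s = (n - 1) / fs))
}

# Closed-form oracle for the plateau detector on the exponential trend:
# the windowed regression slope of dp * (1 - exp(-t/tau)) equals the
# instantaneous slope near the window centre, so the earliest compliant
# window starts where dp/tau * exp(-(t + w/2)/tau) drops to slope_max
# (mmHg/min converted to mmHg/s); the level criterion binds earlier only
# for tiny dp.
expected_plateau_onset_s <- function(dp, tau, slope_max_mmHg_min = 0.2,
                                     window_s = 60) {
  t_slope <- tau * log((dp / tau) / (slope_max_mmHg_min / 60)) - window_s / 2
  max(t_slope, 0)
}

# Cohort calibration anchors used by the recovery tests: mean and SD of the
# generating distributions (flow mL/min, dV_ART mL, dP_CC mmHg, dV_INF mL,
# dP_INF mmHg, cardiac cycle s).
cohort_anchors <- function() {
  list(
    flow = c(mean = 426, sd = 102),
    dv_art = c(mean = 6.0, sd = 2.0),
    dp_cc = c(mean = 3.0, sd = 1.5),
    dv_inf = c(mean = 17, sd = 6),
    dp_inf = c(mean = 20, sd = 9),
    cycle_s = c(mean = 0.83, sd = 0.15)
  )
}
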