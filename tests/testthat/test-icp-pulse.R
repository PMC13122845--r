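# Baseline selection, cardiac frequency estimation, FFT filtering, pulse
# segmentation and ensemble averaging.

make_flat_recording <- function(baseline_s, fs = 100, infusion_start = NULL,
                                total_s = NULL) {
  if (is.null(infusion_start)) infusion_start <- baseline_s
  if (is.null(total_s)) total_s <- infusion_start + 200
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  icp_recording(t, fs, annotations = list(   # trace encodes its own time
    baseline_start_s = 0, baseline_end_s = baseline_s,
    infusion_start_s = infusion_start, infusion_rate_ml_per_min = 1.5,
    recording_end_s = (n - 1) / fs))
}

test_that("select_baseline takes the window ending gap_s before infusion", {
  rec <- make_flat_recording(baseline_s = 300)
  seg <- select_baseline(rec)                 # defaults: 30 s, gap 10 s
  # trace values equal time, so the segment should span [260, 290) s
  expect_equal(length(seg$values_mmHg), 3000L)
  expect_equal(seg$values_mmHg[1], 260)
  expect_lt(max(seg$values_mmHg), 290)
})

test_that("short baselines fall back with a warning, too-short error", {
  rec20 <- make_flat_recording(baseline_s = 20)
  expect_warning(seg <- select_baseline(rec20), "full")
  expect_equal(length(seg$values_mmHg) / seg$sampling_hz, 20, tolerance = 0.01)

  rec5 <- make_flat_recording(baseline_s = 5)
  expect_error(suppressWarnings(select_baseline(rec5)), "too short")
})

test_that("cardiac frequency is located within one bin, respiration ignored", {
  fs <- 100; t <- (0:(30 * fs - 1)) / fs
  bin <- 1 / 30
  tone <- icp_segment(12 + 1.5 * sin(2 * pi * 1.2 * t), fs)
  expect_lt(abs(estimate_cardiac_frequency(tone) - 1.2), bin + 1e-9)

  both <- icp_segment(12 + 1.5 * sin(2 * pi * 1.2 * t) +
                        3.0 * sin(2 * pi * 0.25 * t), fs)
  expect_lt(abs(estimate_cardiac_frequency(both) - 1.2), bin + 1e-9)

  flat <- icp_segment(rep(12, 30 * fs), fs)
  expect_error(estimate_cardiac_frequency(flat), "no cardiac spectral peak")
})

test_that("slow hearts below the search band are recovered via the subharmonic", {
  set.seed(3)
  seg <- make_baseline_segment(hr_bpm = 43, p2p = 3, noise_sd = 0.1)
  f <- estimate_cardiac_frequency(seg)
  expect_equal(f, 43 / 60, tolerance = 0.05)
})

test_that("fft_bandpass keeps the cardiac tone and DC, removes respiration", {
  fs <- 100; dur <- 40; t <- (0:(dur * fs - 1)) / fs   # 40 s: all tones bin-centred
  tone <- 1.5 * sin(2 * pi * 1.2 * t)
  resp <- 3.0 * sin(2 * pi * 0.25 * t)

  seg1 <- icp_segment(12 + tone, fs)
  out1 <- fft_bandpass(seg1, f_c = 1.2)
  expect_lt(max(abs(out1$values_mmHg - (12 + tone))), 0.01 * 1.5)

  seg2 <- icp_segment(12 + tone + resp, fs)
  out2 <- fft_bandpass(seg2, f_c = 1.2)
  # residual power outside the kept band below 0.1% of respiration power
  spec_out <- Mod(fft(out2$values_mmHg - mean(out2$values_mmHg)))^2
  freq <- (seq_along(spec_out) - 1) / length(spec_out) * fs
  fabs <- pmin(freq, fs - freq)
  keep <- c(0.66 * 1.2, 12)
  resid <- sum(spec_out[fabs < keep[1] | fabs > keep[2]])
  resp_power <- sum(Mod(fft(resp))^2)
  expect_lt(resid, 1e-3 * resp_power)

  out3 <- fft_bandpass(seg2, f_c = 1.2, keep_dc = FALSE)
  expect_lt(abs(mean(out3$values_mmHg)), 1e-10)

  expect_error(fft_bandpass(seg1, f_c = 1.2, keep = c(2, 1)), "empty")
})

test_that("fft_bandpass is idempotent and supports a tapered band edge", {
  set.seed(9)
  seg <- make_baseline_segment(p2p = 3, resp_amp = 2, noise_sd = 0.2)
  once <- fft_bandpass(seg, 1.2)
  twice <- fft_bandpass(once, 1.2)
  expect_equal(twice$values_mmHg, once$values_mmHg, tolerance = 1e-10)

  tap <- fft_bandpass(seg, 1.2, taper_hz = 0.2)
  expect_equal(length(tap$values_mmHg), length(seg$values_mmHg))
  # taper must still pass the cardiac band untouched
  expect_equal(mean(tap$values_mmHg), mean(once$values_mmHg),
               tolerance = 1e-8)
})

test_that("pulse segmentation matches a brute-force local-maximum oracle", {
  fs <- 100; t <- (0:(30 * fs - 1)) / fs
  x <- 12 + 1.5 * sin(2 * pi * 1.2 * t)
  seg <- icp_segment(x, fs)
  pulses <- segment_pulses(seg, f_c = 1.2)

  # oracle: plain scan for local maxima (no thresholds needed on a clean tone)
  n <- length(x)
  oracle_peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  expect_equal(length(pulses), length(oracle_peaks) - 1L)
  expect_equal(length(pulses), 35L)   # floor(30 * 1.2) - 1 complete pulses
})

test_that("beat-length screening discards an ectopic-like long beat", {
  fs <- 100
  # 29 normal beats of 0.8 s and one 40% longer beat spliced in
  period <- 0.8
  durs <- c(rep(period, 12), 1.4 * period, rep(period, 17))
  starts <- c(0, cumsum(durs))
  total <- sum(durs)
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  b <- findInterval(t, starts)
  ph <- (t - starts[b]) / durs[b]
  x <- 12 + 1.5 * cos(2 * pi * ph)          # peak-aligned beats
  seg <- icp_segment(x, fs)
  expect_message(pulses <- segment_pulses(seg, f_c = 1 / period),
                 "discarded 1")
  # oracle: one peak per beat onset except the undetectable t = 0 boundary,
  # so 29 peaks -> 28 complete pulses -> 27 after the long beat is dropped
  expect_equal(length(pulses), length(durs) - 3L)

  flat <- icp_segment(rep(12, 3000), fs)
  expect_error(segment_pulses(flat, f_c = 1.2), "peak")
})

test_that("average_pulse reproduces identical beats and averages noise as 1/sqrt(N)", {
  one <- 12 + 1.5 * cos(2 * pi * (0:63) / 64)
  avg <- average_pulse(rep(list(one), 5), sampling_hz = 100)
  expect_equal(avg$n_beats, 5L)
  expect_equal(avg$period_s, 0.64)
  expect_equal(max(avg$values_mmHg) - max(one), 0, tolerance = 1e-12)
  expect_equal(avg$delta_p_cc_mmHg, max(one) - min(one), tolerance = 1e-12)

  # beats of length 64 resample onto the 32-grid without interpolation, so
  # averaged noise variance shrinks exactly as sigma^2 / N
  set.seed(21)
  sigma <- 0.5
  reps <- vapply(1:400, function(i) {
    noisy <- lapply(1:4, function(j) one + rnorm(64, 0, sigma))
    a <- average_pulse(noisy, sampling_hz = 100)
    clean <- average_pulse(rep(list(one), 4), sampling_hz = 100)
    sd(a$values_mmHg - clean$values_mmHg)
  }, numeric(1))
  expect_equal(mean(reps), sigma / 2, tolerance = 0.05)

  expect_error(average_pulse(list(one, one, numeric(1)), sampling_hz = 100),
               "degenerate")
  expect_error(average_pulse(list(one, one), sampling_hz = 100), "at least 3")
})

test_that("sinusoidal beats recover their peak-to-peak amplitude", {
  set.seed(5)
  seg <- make_baseline_segment(hr_bpm = 75, p2p = 3)
  pulse <- run_pulse_chain(seg)
  expect_equal(pulse$delta_p_cc_mmHg, 3, tolerance = 0.02)
})

test_that("end-to-end chain recovers the cardiac amplitude under respiration and noise", {
  fs <- 100; t <- (0:(30 * fs - 1)) / fs
  set.seed(13)
  x <- 12 + 1.5 * sin(2 * pi * 1.2 * t) + 2.0 * sin(2 * pi * 0.25 * t) +
    rnorm(length(t), 0, 0.1)
  pulse <- run_pulse_chain(icp_segment(x, fs))
  expect_equal(pulse$delta_p_cc_mmHg, 3.0, tolerance = 0.05)
})

test_that("dP_CC is invariant to a constant pressure offset", {
  set.seed(17)
  n <- 3000
  base <- make_baseline_segment(p2p = 2.5, resp_amp = 1, noise_sd = 0.2)
  shifted <- icp_segment(base$values_mmHg + 25, base$sampling_hz)
  p1 <- run_pulse_chain(base)
  p2 <- run_pulse_chain(shifted)
  expect_equal(p1$delta_p_cc_mmHg, p2$delta_p_cc_mmHg, tolerance = 1e-8)
})

test_that("recovered beat period matches the generator on jitter-free fixtures", {
  set.seed(29)
  for (hr in c(55, 72, 95, 120)) {
    seg <- make_baseline_segment(hr_bpm = hr, p2p = 3, jitter = 0)
    pulse <- run_pulse_chain(seg)
    expect_equal(pulse$period_s, 60 / hr, tolerance = 0.02)
  }
})
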