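# Seeded synthetic cohorts: pulsatile arterial flow curves, baseline +
# infusion ICP recordings and a ground-truth table, calibrated by default to
# an elderly cohort investigated for normal pressure hydrocephalus
# (mean arterial inflow 426 +/- 102 mL/min, MRI heart rate 74 +/- 14 BPM,
# baseline pulse amplitude 3.0 +/- 1.5 mmHg, infusion pressure rise
# 20 +/- 9 mmHg at 1.5 mL/min). The plateau trend is a single exponential
# approach, the simplest model that has a plateau and closed-form oracles;
# its time constant is calibrated so that the plateau detector's
# infusion-to-plateau duration lands at the cohort scale of ~11-12 min
# (infused volume ~17 mL at 1.5 mL/min).

#' Default cohort generator configuration
#'
#' Truncated-normal distribution parameters (`mean, sd, lower, upper`) for
#' every subject-level truth field, plus the heart-rate coupling between the
#' MRI and infusion sessions (Gaussian copula correlation `hr_rho`, additive
#' offset `hr_offset_bpm`: infusion heart rate runs slightly lower than MRI
#' heart rate but is strongly rank-correlated with it).
#'
#' @param n_subjects Cohort size.
#' @param ... Named overrides of individual entries.
#' @return A list of class `cohort_config`.
#' @export
default_cohort_config <- function(n_subjects = 108L, ...) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    q_mean_ml_per_min = c(426, 102, 150, 800),
    hr_mri_bpm = c(74, 14, 40, 150),
    hr_offset_bpm = -2,
    hr_rho = 0.85,
    pulse_p2p_mmHg = c(3.0, 1.5, 0.5, 5.5),
    icp_b_mmHg = c(10, 4, 4, 16),
    delta_p_inf_mmHg = c(20, 9, 5, 35),
    tau_s = c(218, 40, 60, 400),
    resp_freq_hz = c(0.25, 0.05, 0.10, 0.45),
    resp_amp_mmHg = c(1.5, 0.5, 0.2, 4),
    noise_sd_mmHg = c(0.3, 0.1, 0.05, 0.6),
    vessel_share_mean = c(ICAL = 0.38, ICAR = 0.38, BA = 0.24),
    vessel_share_sd = 0.03,
    pulsatility = 0.8,
    beat_jitter = 0.03,
    infusion_rate_ml_per_min = 1.5,
    sampling_hz = 100,
    baseline_s = 300,
    post_plateau_s = 300
  )
  over <- list(...)
  for (key in names(over)) {
    if (!key %in% names(cfg)) stopf("unknown generator entry '%s'", key)
    cfg[[key]] <- over[[key]]
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Draw per-subject ground truth
#'
#' Samples `n` subjects from the configured truncated-normal distributions
#' using the current RNG stream (seed it with `set.seed()` or use
#' [simulate_cohort()], which does so from its master seed).
#'
#' @param config A [default_cohort_config()] list.
#' @param n Number of subjects; defaults to `config$n_subjects`.
#' @return A `data.frame`, one row per subject, with all truth fields.
#' @export
draw_subject_truths <- function(config = default_cohort_config(),
                                n = config$n_subjects) {
  tn <- function(par, n) rtruncnorm(n, par[1], par[2], par[3], par[4])
  # Coupled heart rates via a Gaussian copula on the latent scale.
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- config$hr_rho
  hrp <- config$hr_mri_bpm
  hr_mri <- hrp[1] + hrp[2] * z1
  hr_inf <- hrp[1] + config$hr_offset_bpm +
    hrp[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  bad <- hr_mri < hrp[3] | hr_mri > hrp[4] | hr_inf < hrp[3] | hr_inf > hrp[4]
  while (any(bad)) {
    k <- sum(bad)
    z1b <- stats::rnorm(k); z2b <- stats::rnorm(k)
    hr_mri[bad] <- hrp[1] + hrp[2] * z1b
    hr_inf[bad] <- hrp[1] + config$hr_offset_bpm +
      hrp[2] * (rho * z1b + sqrt(1 - rho^2) * z2b)
    bad <- hr_mri < hrp[3] | hr_mri > hrp[4] | hr_inf < hrp[3] |
      hr_inf > hrp[4]
  }
  shares <- matrix(stats::rnorm(3L * n, rep(config$vessel_share_mean, each = n),
                                config$vessel_share_sd), ncol = 3L)
  shares <- pmax(shares, 0.05)
  shares <- shares / rowSums(shares)
  colnames(shares) <- names(config$vessel_share_mean)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    q_mean_ml_per_min = tn(config$q_mean_ml_per_min, n),
    share_ical = shares[, "ICAL"],
    share_icar = shares[, "ICAR"],
    share_ba = shares[, "BA"],
    hr_mri_bpm = hr_mri,
    hr_inf_bpm = hr_inf,
    pulse_p2p_mmHg = tn(config$pulse_p2p_mmHg, n),
    icp_b_mmHg = tn(config$icp_b_mmHg, n),
    delta_p_inf_mmHg = tn(config$delta_p_inf_mmHg, n),
    tau_s = tn(config$tau_s, n),
    resp_freq_hz = tn(config$resp_freq_hz, n),
    resp_amp_mmHg = tn(config$resp_amp_mmHg, n),
    noise_sd_mmHg = tn(config$noise_sd_mmHg, n),
    stringsAsFactors = FALSE
  )
}

#' Simulate the three arterial flow curves of one subject
#'
#' Deterministic given the truth row: each vessel carries its share of the
#' subject's mean flow modulated by a common pulsatile waveform
#' `w(t) = 1 + a * (g(t) - mean(g))` with `g` a Gaussian systolic bump
#' (centre 0.15 T, width 0.08 T) and pulsatility `a` (default 0.8). The
#' sample mean of `w` is exactly 1, so the vessel means sum to the subject's
#' mean flow by construction.
#'
#' @param truth One row of [draw_subject_truths()].
#' @param pulsatility Pulsatility factor `a` (>= 0).
#' @param n_frames Frames per cardiac cycle.
#' @return Named list of [flow_curve] objects `ICAL`, `ICAR`, `BA`.
#' @export
simulate_flow_curves <- function(truth, pulsatility = 0.8,
                                 n_frames = N_FRAMES) {
  T_s <- 60 / truth$hr_mri_bpm
  ph <- (seq_len(n_frames) - 1L) / n_frames
  g <- exp(-0.5 * ((ph - 0.15) / 0.08)^2)
  w <- 1 + pulsatility * (g - mean(g))
  if (any(w < 0)) {
    stopf("pulsatility %g drives the flow waveform negative", pulsatility)
  }
  shares <- c(ICAL = truth$share_ical, ICAR = truth$share_icar,
              BA = truth$share_ba)
  out <- lapply(names(shares), function(v) {
    flow_curve(shares[[v]] * truth$q_mean_ml_per_min * w, period_s = T_s,
               vessel_id = v, units = "ml_per_min")
  })
  names(out) <- names(shares)
  out
}

# Triphasic ICP pulse template on a normalized cycle: Gaussian sub-peaks
# P1 (percussion), P2 (tidal, 1.1 x P1 so the tidal wave dominates as in
# impaired compliance) and P3 (dicrotic); zero-mean, unit peak-to-peak.
#' @keywords internal
#' @noRd
pulse_template <- function(n = 512L) {
  ph <- (seq_len(n) - 1L) / n
  comp <- function(c0, s, a) {
    # wrap neighbouring cycles so the template is periodic
    a * (exp(-0.5 * ((ph - c0) / s)^2) +
         exp(-0.5 * ((ph - c0 - 1) / s)^2) +
         exp(-0.5 * ((ph - c0 + 1) / s)^2))
  }
  w <- comp(0.12, 0.06, 1.0) + comp(0.30, 0.10, 1.1) + comp(0.55, 0.12, 0.8)
  w <- w - mean(w)
  w / (max(w) - min(w))
}

#' Simulate one lumbar infusion ICP recording
#'
#' Signal model: `s(t) = trend + pulse + respiration + noise`.
#' The trend sits at the subject's baseline pressure and, from infusion
#' start, rises as a single exponential `delta_p_inf * (1 - exp(-t'/tau))`
#' towards the plateau. The cardiac pulse is a periodic three-sub-peak
#' waveform scaled to the subject's true peak-to-peak amplitude, with
#' beat-to-beat period jitter; respiration is a sinusoid; noise is white.
#' Durations: `baseline_s` of baseline, infusion for `6 * tau` (1.5 times
#' the ~4 tau the plateau detector needs), then `post_plateau_s` more.
#'
#' @param truth One row of [draw_subject_truths()].
#' @param config A [default_cohort_config()] list (sampling rate, durations,
#'   jitter, infusion rate).
#' @return An [icp_recording] with filled annotations.
#' @export
simulate_icp <- function(truth, config = default_cohort_config()) {
  fs <- config$sampling_hz
  t_inf <- config$baseline_s
  dur <- config$baseline_s + 6 * truth$tau_s + config$post_plateau_s
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1L) / fs

  trend <- rep(truth$icp_b_mmHg, n)
  post <- t >= t_inf
  trend[post] <- trend[post] +
    truth$delta_p_inf_mmHg * (1 - exp(-(t[post] - t_inf) / truth$tau_s))

  # beat grid with period jitter
  period <- 60 / truth$hr_inf_bpm
  n_beats <- ceiling(dur / (period * (1 - 3 * config$beat_jitter))) + 2L
  durs <- period * (1 + config$beat_jitter * stats::rnorm(n_beats))
  durs <- pmax(durs, 0.4 * period)
  starts <- c(0, cumsum(durs))
  beat <- findInterval(t, starts)
  phase <- (t - starts[beat]) / durs[beat]
  tmpl <- pulse_template()
  pulse <- truth$pulse_p2p_mmHg *
    tmpl[pmin(length(tmpl), floor(phase * length(tmpl)) + 1L)]

  resp <- truth$resp_amp_mmHg * sin(2 * pi * truth$resp_freq_hz * t)
  noise <- stats::rnorm(n, 0, truth$noise_sd_mmHg)

  icp_recording(
    trend + pulse + resp + noise, fs,
    annotations = list(
      baseline_start_s = 0,
      baseline_end_s = t_inf,
      infusion_start_s = t_inf,
      infusion_rate_ml_per_min = config$infusion_rate_ml_per_min,
      recording_end_s = (n - 1L) / fs
    )
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws `config$n_subjects` ground-truth rows from the master seed and
#' generates every subject's flow curves and ICP recording. With `out_dir`
#' set, all files are written in the package's on-disk formats together with
#' `manifest.csv` and `truth.csv`; otherwise the objects are returned
#' in memory. Same config + seed reproduces identical output.
#'
#' @param seed Master seed; the only source of randomness.
#' @param config A [default_cohort_config()] list.
#' @param out_dir Output directory, or `NULL` for in-memory objects.
#' @return A list: `truth` (data.frame), `subjects` (list with `flows` and
#'   `icp` per subject; omitted when writing to disk), `manifest`
#'   (path or `NULL`).
#' @export
simulate_cohort <- function(seed, config = default_cohort_config(),
                            out_dir = NULL) {
  set.seed(seed)
  truth <- draw_subject_truths(config)
  n <- nrow(truth)
  write_files <- !is.null(out_dir)
  if (write_files) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    flows <- simulate_flow_curves(tr, pulsatility = config$pulsatility)
    icp <- simulate_icp(tr, config)
    if (write_files) {
      id <- tr$subject_id
      fp <- sprintf("%s_%s.csv", id, tolower(names(flows)))
      for (k in seq_along(flows)) {
        write_flow_curve(flows[[k]], file.path(out_dir, fp[k]))
      }
      icp_f <- sprintf("%s_icp.csv", id)
      ann_f <- sprintf("%s_icp.yaml", id)
      write_icp_recording(icp, file.path(out_dir, icp_f),
                          file.path(out_dir, ann_f))
      rows[[i]] <- data.frame(subject_id = id,
                              flow_ical = fp[1], flow_icar = fp[2],
                              flow_ba = fp[3], icp = icp_f,
                              annotations = ann_f, group = "full",
                              stringsAsFactors = FALSE)
    } else {
      subjects[[i]] <- list(flows = flows, icp = icp)
    }
  }

  manifest <- NULL
  if (write_files) {
    manifest <- file.path(out_dir, "manifest.csv")
    write_cohort_manifest(do.call(rbind, rows), manifest)
    data.table::fwrite(truth, file.path(out_dir, "truth.csv"))
    subjects <- NULL
  }
  list(truth = truth, subjects = subjects, manifest = manifest)
}
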