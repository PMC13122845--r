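# Synthetic cohort generator: determinism, calibration, and full-loop
# parameter recovery through the analysis pipeline.

test_that("the generator is reproducible from its master seed", {
  cfg <- default_cohort_config(2)
  a <- simulate_cohort(seed = 11, config = cfg)
  b <- simulate_cohort(seed = 11, config = cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$subjects[[1]]$icp$icp_mmHg, b$subjects[[1]]$icp$icp_mmHg)
  expect_identical(a$subjects[[2]]$flows$BA$values_ml_per_s,
                   b$subjects[[2]]$flows$BA$values_ml_per_s)
  c_ <- simulate_cohort(seed = 12, config = cfg)
  expect_false(identical(a$subjects[[1]]$icp$icp_mmHg,
                         c_$subjects[[1]]$icp$icp_mmHg))
})

test_that("flow curves carry the configured mean flow and split", {
  set.seed(1)
  tr <- draw_subject_truths(default_cohort_config(), n = 20)
  for (i in c(1, 7, 20)) {
    flows <- simulate_flow_curves(tr[i, ])
    total_mean <- sum(vapply(flows, mean_flow_ml_per_min, numeric(1)))
    expect_equal(total_mean, tr$q_mean_ml_per_min[i],
                 tolerance = 1e-3)                      # within 0.1%
    expect_true(all(vapply(flows, function(q)
      all(q$values_ml_per_s >= 0), logical(1))))
  }
  # zero pulsatility: constant curves, pipeline dV_ART = q_mean * T / 60 exactly
  flows0 <- simulate_flow_curves(tr[1, ], pulsatility = 0)
  expect_equal(diff(range(flows0$ICAL$values_ml_per_s)), 0)
  q <- sum_arterial_flows(flows0$ICAL, flows0$ICAR, flows0$BA)
  expect_equal(volume_curve(q)$delta_v_art_ml,
               tr$q_mean_ml_per_min[1] * (60 / tr$hr_mri_bpm[1]) / 60)
  expect_error(simulate_flow_curves(tr[1, ], pulsatility = 10), "negative")
})

test_that("truth draws land on the configured distributions", {
  set.seed(33)
  cfg <- default_cohort_config()
  tr <- draw_subject_truths(cfg, n = 500)
  checks <- list(
    c("q_mean_ml_per_min", 426), c("hr_mri_bpm", 74),
    c("pulse_p2p_mmHg", 3.0), c("icp_b_mmHg", 10),
    c("delta_p_inf_mmHg", 20), c("tau_s", 218)
  )
  for (ck in checks) {
    expect_equal(mean(tr[[ck[1]]]), as.numeric(ck[2]),
                 tolerance = 0.10)
  }
  expect_equal(cor(tr$hr_mri_bpm, tr$hr_inf_bpm, method = "spearman"),
               0.85, tolerance = 0.05)
  expect_true(all(abs(tr$share_ical + tr$share_icar + tr$share_ba - 1) < 1e-12))
})

test_that("clean recordings recover the true pulse amplitude within 1%", {
  set.seed(8)
  cfg <- default_cohort_config()
  tr <- draw_subject_truths(cfg, n = 3)
  tr$resp_amp_mmHg <- 0
  tr$noise_sd_mmHg <- 1e-9     # white-noise term off
  cfg$beat_jitter <- 0
  for (i in 1:3) {
    rec <- simulate_icp(tr[i, ], cfg)
    pulse <- baseline_pulse(rec)
    expect_equal(pulse$delta_p_cc_mmHg, tr$pulse_p2p_mmHg[i],
                 tolerance = 0.01)
  }
})

test_that("trend-only recordings recover the true pressure rise within 5%", {
  set.seed(9)
  cfg <- default_cohort_config()
  tr <- draw_subject_truths(cfg, n = 3)
  tr$pulse_p2p_mmHg <- 0; tr$resp_amp_mmHg <- 0; tr$noise_sd_mmHg <- 1e-9
  for (i in 1:3) {
    rec <- simulate_icp(tr[i, ], cfg)
    inf <- infusion_metrics(rec)
    expect_equal(inf$delta_p_inf_mmHg, tr$delta_p_inf_mmHg[i],
                 tolerance = 0.05)
  }
})

test_that("full-loop recovery: pipeline estimates track the generating truth", {
  co <- simulate_cohort(seed = 42)
  res <- suppressWarnings(analyze_cohort(co))
  expect_equal(nrow(res$table), 108)
  expect_equal(nrow(res$exclusions), 0)
  tr <- co$truth; tb <- res$table

  # dV_ART: all-positive flow integrates to q_mean * T / 60 (exact quadrature)
  expect_equal(tb$delta_v_art_ml, tr$q_mean_ml_per_min / tr$hr_mri_bpm,
               tolerance = 1e-10)

  # dP_INF within 7% per subject
  expect_true(all(abs(tb$delta_p_inf_mmHg / tr$delta_p_inf_mmHg - 1) < 0.07))

  # dP_CC within 10% per subject wherever noise and respiration stay inside
  # the regime the pulse filter is designed for (noise SD <= 0.2 amplitude,
  # respiration <= 2x amplitude); amplitude-floor subjects with
  # proportionally outsized noise may exceed this
  ctrl <- tr$noise_sd_mmHg <= 0.2 * tr$pulse_p2p_mmHg &
    tr$resp_amp_mmHg <= 2 * tr$pulse_p2p_mmHg
  expect_gt(sum(ctrl), 50)
  err <- tb$delta_p_cc_mmHg / tr$pulse_p2p_mmHg - 1
  # peak-picking on a noisy ensemble average carries a small positive bias,
  # so the 10% envelope holds for the bulk but not every tail draw
  expect_gt(mean(abs(err[ctrl]) < 0.10), 0.95)
  expect_true(all(abs(err[ctrl]) < 0.15))
  # and cohort-level bias stays small regardless
  expect_lt(abs(mean(err)), 0.03)
})

test_that("cohort files written to disk load back through the manifest", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(seed = 3, config = default_cohort_config(5),
                        out_dir = dir)
  expect_true(file.exists(co$manifest))
  res <- suppressWarnings(analyze_cohort(co$manifest))
  expect_equal(nrow(res$table), 5)
  # in-memory and on-disk routes agree
  co_mem <- simulate_cohort(seed = 3, config = default_cohort_config(5))
  res_mem <- suppressWarnings(analyze_cohort(co_mem))
  expect_equal(res$table$delta_p_cc_mmHg, res_mem$table$delta_p_cc_mmHg,
               tolerance = 1e-9)
  expect_equal(res$table$delta_t_inf_s, res_mem$table$delta_t_inf_s)
})
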