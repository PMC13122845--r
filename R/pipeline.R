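# Per-subject and cohort-level drivers tying the flow, pulse and infusion
# analyses together.

#' Analyze one subject
#'
#' Runs the complete per-subject pipeline: sum the three arterial flow
#' curves, integrate to the volume curve (both the total-volume and the
#' mean-subtracted pulsatile convention are reported), extract the average
#' baseline ICP pulse and its amplitude, analyze the infusion phase, and
#' form both compliance estimates.
#'
#' @param flows Named list of [flow_curve]s (`ICAL`, `ICAR`, `BA`), e.g.
#'   from [read_flow_curves()] or [simulate_flow_curves()].
#' @param icp An [icp_recording].
#' @param subject_id Identifier carried into the output row.
#' @param config An [analysis_config()] list.
#' @return A one-row `data.frame` with columns `subject_id`,
#'   `mean_arterial_flow_ml_per_min`, `cardiac_period_mri_s`, `hr_mri_bpm`,
#'   `delta_v_art_ml`, `delta_v_art_pulsatile_ml`, `delta_p_cc_mmHg`,
#'   `cardiac_period_inf_s`, `hr_inf_bpm`, `n_beats`,
#'   `c_physio_ml_per_mmHg`, and all [infusion_metrics()] columns.
#' @export
analyze_subject <- function(flows, icp, subject_id = NA_character_,
                            config = analysis_config()) {
  stopifnot(is.list(flows), inherits(icp, "icp_recording"))
  q_art <- sum_arterial_flows(flows$ICAL, flows$ICAR, flows$BA,
                              clamp_negative = config$flow$clamp_negative)
  v_total <- volume_curve(q_art, subtract_mean = config$flow$subtract_mean)
  v_puls <- volume_curve(q_art, subtract_mean = TRUE)

  pulse <- baseline_pulse(icp, config)
  inf <- infusion_metrics(icp, config = config)

  dv <- v_total$delta_v_art_ml
  dp <- pulse$delta_p_cc_mmHg
  out <- data.frame(
    subject_id = subject_id,
    mean_arterial_flow_ml_per_min = mean_flow_ml_per_min(q_art),
    cardiac_period_mri_s = q_art$period_s,
    hr_mri_bpm = 60 / q_art$period_s,
    delta_v_art_ml = dv,
    delta_v_art_pulsatile_ml = v_puls$delta_v_art_ml,
    delta_p_cc_mmHg = dp,
    cardiac_period_inf_s = pulse$period_s,
    hr_inf_bpm = 60 / pulse$period_s,
    n_beats = pulse$n_beats,
    c_physio_ml_per_mmHg = c_physio(dv, dp),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(unclass(inf)))
}

#' Analyze a cohort
#'
#' Accepts either a manifest path (files are loaded through the package
#' readers) or the in-memory `subjects` list of [simulate_cohort()]. Each
#' failing subject is excluded with a logged reason, never silently. On the
#' assembled table the standard outcome family is compared pairwise
#' (measurement duration, volume change, pressure change, compliance:
#' infusion vs physiological condition) with the normality-gated paired
#' test and a Holm correction across that family; the heart-rate comparison
#' between the two sessions is run alongside as its own single-member
#' family. Cohort means of ratio metrics (both compliances) are means of
#' per-subject ratios, never ratios of cohort means. A Spearman correlation
#' matrix over the standard variable set and a descriptive summary complete
#' the result.
#'
#' @param cohort Manifest CSV path, or a list as returned by
#'   [simulate_cohort()] with `out_dir = NULL`.
#' @param config An [analysis_config()] list.
#' @return A list of class `cohort_analysis`: `table` (per-subject
#'   metrics), `stats` (paired comparisons with `p_holm`), `correlations`
#'   (a [spearman_matrix()]), `summary` (a [cohort_summary()]),
#'   `exclusions` (data.frame of skipped subjects and reasons).
#' @export
analyze_cohort <- function(cohort, config = analysis_config()) {
  if (is.character(cohort)) {
    manifest <- read_cohort_manifest(cohort)
    loader <- function(i) {
      list(flows = read_flow_curves(c(manifest$flow_ical[i],
                                      manifest$flow_icar[i],
                                      manifest$flow_ba[i])),
           icp = read_icp_recording(manifest$icp[i],
                                    manifest$annotations[i]),
           id = manifest$subject_id[i])
    }
    n <- nrow(manifest)
  } else if (is.list(cohort) && !is.null(cohort$subjects)) {
    loader <- function(i) {
      list(flows = cohort$subjects[[i]]$flows,
           icp = cohort$subjects[[i]]$icp,
           id = cohort$truth$subject_id[i])
    }
    n <- length(cohort$subjects)
  } else {
    stopf("cohort must be a manifest path or a simulate_cohort() result")
  }

  rows <- vector("list", n)
  excl <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      s <- loader(i)
      suppressMessages(
        analyze_subject(s$flows, s$icp, subject_id = s$id, config = config))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      id <- tryCatch(loader(i)$id, error = function(e) sprintf("row %d", i))
      warnf("excluding subject %s: %s", id, conditionMessage(res))
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- res
    }
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(table) || nrow(table) < 5L) {
    stopf("fewer than 5 subjects analyzed; cohort statistics not meaningful")
  }

  alpha <- config$stats$alpha
  fam <- rbind(
    paired_compare(table$delta_t_inf_s / 60, table$cardiac_period_inf_s,
                   alpha, "duration: infusion (min) vs cardiac cycle (s)"),
    paired_compare(table$delta_v_inf_ml, table$delta_v_art_ml,
                   alpha, "volume change: dV_INF vs dV_ART"),
    paired_compare(table$delta_p_inf_mmHg, table$delta_p_cc_mmHg,
                   alpha, "pressure change: dP_INF vs dP_CC"),
    paired_compare(table$c_inf_ml_per_mmHg, table$c_physio_ml_per_mmHg,
                   alpha, "compliance: C_INF vs C_physio")
  )
  fam$family <- "outcomes"
  fam$p_holm <- holm_adjust(fam$p_raw)
  hr <- paired_compare(table$hr_mri_bpm, table$hr_inf_bpm, alpha,
                       "heart rate: MRI vs infusion")
  hr$family <- "heart-rate"
  hr$p_holm <- hr$p_raw
  stats <- rbind(fam, hr)

  vars <- c("c_physio_ml_per_mmHg", "c_inf_ml_per_mmHg", "delta_v_art_ml",
            "rout_mmHg_per_ml_per_min", "icp_b_mmHg", "icp_p_mmHg",
            "hr_mri_bpm", "hr_inf_bpm")
  correlations <- spearman_matrix(table, vars)

  structure(
    list(table = table, stats = stats, correlations = correlations,
         summary = cohort_summary(table),
         exclusions = if (length(excl)) do.call(rbind, excl) else
           data.frame(subject_id = character(0), reason = character(0))),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subject(s), %d excluded\n",
              nrow(x$table), nrow(x$exclusions)))
  key <- c("delta_v_art_ml", "delta_p_cc_mmHg", "c_physio_ml_per_mmHg",
           "delta_v_inf_ml", "delta_p_inf_mmHg", "c_inf_ml_per_mmHg")
  s <- x$summary[x$summary$variable %in% key, ]
  cat("\nKey metrics (mean +/- SD):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-26s %6.2f +/- %.2f\n", s$variable[i], s$mean[i],
                s$sd[i]))
  }
  cat("\nPaired comparisons:\n")
  for (i in seq_len(nrow(x$stats))) {
    cat(sprintf("  %-45s %-9s p_holm = %.3g\n", x$stats$label[i],
                x$stats$test_used[i], x$stats$p_holm[i]))
  }
  invisible(x)
}
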