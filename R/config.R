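# Analysis configuration: every threshold of the pipeline in one place.

#' Analysis configuration
#'
#' Returns the full set of tunable parameters of the per-subject pipeline
#' with their defaults. Any subset can be overridden via `...` using nested
#' lists, e.g. `analysis_config(pulse = list(window_s = 20))`.
#'
#' Sections:
#' \describe{
#'   \item{flow}{`subtract_mean` (default `FALSE`, total-volume convention
#'     for dV_ART), `clamp_negative` (default `FALSE`).}
#'   \item{pulse}{baseline selection (`window_s` 30 s, `gap_s` 10 s),
#'     cardiac search band (`cardiac_band_hz` 0.8-2.5 Hz), FFT filter
#'     (`keep_band_hz` `NULL` = `[0.66 f_c, min(15, 10 f_c)]`, `keep_dc`
#'     `TRUE`, `taper_hz` 0), beat segmentation (`min_sep_factor` 0.6,
#'     `prominence_factor` 0.25, `length_tol` 0.25), `n_points` 32.}
#'   \item{plateau}{`window_s` 60 s, `slope_max_mmHg_per_min` 0.2,
#'     `level_tol_mmHg` 1.0, `smooth_s` 10 s, `hop_s` 1 s.}
#'   \item{stats}{`alpha` 0.05 for the Shapiro-Wilk normality gate.}
#' }
#'
#' @param ... Named nested lists overriding individual entries.
#' @return A nested list of class `csc_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    flow = list(
      subtract_mean = FALSE,
      clamp_negative = FALSE
    ),
    pulse = list(
      window_s = 30,
      gap_s = 10,
      cardiac_band_hz = c(0.8, 2.5),
      keep_band_hz = NULL,
      keep_dc = TRUE,
      taper_hz = 0,
      min_sep_factor = 0.6,
      prominence_factor = 0.25,
      length_tol = 0.25,
      n_points = 32L
    ),
    plateau = list(
      window_s = 60,
      slope_max_mmHg_per_min = 0.2,
      level_tol_mmHg = 1.0,
      smooth_s = 10,
      hop_s = 1
    ),
    stats = list(
      alpha = 0.05
    )
  )
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stopf("unknown config section '%s'", sec)
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        stopf("unknown config entry '%s$%s'", sec, key)
      }
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  structure(cfg, class = "csc_config")
}

#' @export
print.csc_config <- function(x, ...) {
  cat("<csc_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
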