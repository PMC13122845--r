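# Constant-rate lumbar infusion analysis: plateau detection, infused volume,
# pressure rise, infusion-derived compliance C_INF and outflow resistance
# Rout.

#' Detect the ICP plateau after infusion start
#'
#' The cardiac and respiratory components are first removed by a centred
#' moving average (`smooth_s`, default 10 s). Sliding windows of `window_s`
#' are then scanned (hop `hop_s`) from infusion start: the plateau begins at
#' the earliest window whose regression slope is at most `slope_max`
#' (mmHg/min) *and* whose mean lies within `level_tol` mmHg of the largest
#' windowed mean seen from that window onwards — the level condition stops a
#' slow shoulder partway up the rise from being mistaken for the plateau.
#' The plateau extends from that window's start to the end of the recording.
#'
#' @param rec An [icp_recording] with an annotated infusion start.
#' @param window_s Sliding-window length, s.
#' @param slope_max Maximum trend slope inside a plateau window, mmHg/min.
#' @param level_tol Allowed shortfall of a window mean below the maximum
#'   later windowed mean, mmHg.
#' @param smooth_s Moving-average length used to extract the trend, s.
#' @param hop_s Hop between candidate window starts, s.
#' @return A list of class `icp_plateau`: `start_s`, `end_s`,
#'   `delta_t_inf_s` (plateau start minus infusion start), plus the trend
#'   diagnostics `slope_mmHg_per_min` and `window_mean_mmHg` of the chosen
#'   window.
#' @export
detect_plateau <- function(rec, window_s = 60, slope_max = 0.2,
                           level_tol = 1.0, smooth_s = 10, hop_s = 1) {
  stopifnot(inherits(rec, "icp_recording"))
  fs <- rec$sampling_hz
  x <- rec$icp_mmHg
  n <- length(x)
  a <- rec$annotations
  i_inf <- max(1L, floor(a$infusion_start_s * fs) + 1L)
  if ((n - i_inf + 1L) / fs < 2 * window_s) {
    stopf("need at least %g s of post-infusion signal, have %.1f s",
          2 * window_s, (n - i_inf + 1L) / fs)
  }
  trend <- moving_average(x, round(smooth_s * fs))

  w <- max(2L, round(window_s * fs))
  hop <- max(1L, round(hop_s * fs))
  starts <- seq.int(i_inf, n - w + 1L, by = hop)

  # Windowed means and regression slopes in O(n) via cumulative sums.
  cs <- cumsum(c(0, trend))
  ci <- cumsum(c(0, trend * seq_len(n)))
  s_end <- starts + w - 1L
  sum_y <- cs[s_end + 1L] - cs[starts]
  sum_iy <- ci[s_end + 1L] - ci[starts]
  # sum over i = s..s+w-1 of i and i^2, in closed form
  sum_i <- (starts + s_end) * w / 2
  sum_i2 <- s_end * (s_end + 1) * (2 * s_end + 1) / 6 -
    (starts - 1) * starts * (2 * starts - 1) / 6
  slope_per_sample <- (w * sum_iy - sum_i * sum_y) /
    (w * sum_i2 - sum_i^2)
  slope_mmHg_min <- slope_per_sample * fs * 60
  win_mean <- sum_y / w

  later_max <- rev(cummax(rev(win_mean)))
  ok <- slope_mmHg_min <= slope_max & win_mean >= later_max - level_tol
  if (!any(ok)) {
    stopf("no ICP plateau found (no %g-s window with slope <= %g mmHg/min %s",
          window_s, slope_max, "near the terminal level)")
  }
  k <- which(ok)[1]
  start_s <- (starts[k] - 1L) / fs
  structure(
    list(start_s = start_s,
         end_s = min(a$recording_end_s, (n - 1L) / fs),
         delta_t_inf_s = start_s - a$infusion_start_s,
         slope_mmHg_per_min = slope_mmHg_min[k],
         window_mean_mmHg = win_mean[k]),
    class = "icp_plateau"
  )
}

#' @export
print.icp_plateau <- function(x, ...) {
  cat(sprintf(
    "<icp_plateau> [%.0f, %.0f] s; infusion-to-plateau %.1f min (slope %.3f mmHg/min)\n",
    x$start_s, x$end_s, x$delta_t_inf_s / 60, x$slope_mmHg_per_min))
  invisible(x)
}

#' Infusion-phase metrics: dV_INF, dP_INF, C_INF, Rout
#'
#' Baseline mean ICP is taken on the raw annotated baseline window (the
#' pulse filter would strip slow components that belong in a mean), plateau
#' mean on the raw trace over the detected plateau. Then
#' `delta_p_inf = icp_p - icp_b`, `delta_v_inf = rate * delta_t_inf` (rate in
#' mL/min, duration in min), `c_inf = delta_v_inf / delta_p_inf` and
#' `rout = delta_p_inf / rate`. The identity
#' `c_inf * rout = delta_t_inf` (minutes) holds by construction and is a
#' built-in consistency check.
#'
#' @param rec An [icp_recording].
#' @param plateau An [detect_plateau()] result; computed if `NULL`.
#' @param config An [analysis_config()] list (plateau settings are taken
#'   from it when `plateau` is `NULL`).
#' @return A one-row `data.frame` of class `infusion_metrics` with columns
#'   `icp_b_mmHg`, `icp_p_mmHg`, `delta_p_inf_mmHg`, `delta_t_inf_s`,
#'   `delta_v_inf_ml`, `c_inf_ml_per_mmHg`, `rout_mmHg_per_ml_per_min`.
#' @export
infusion_metrics <- function(rec, plateau = NULL,
                             config = analysis_config()) {
  stopifnot(inherits(rec, "icp_recording"))
  if (is.null(plateau)) {
    pc <- config$plateau
    plateau <- detect_plateau(rec, window_s = pc$window_s,
                              slope_max = pc$slope_max_mmHg_per_min,
                              level_tol = pc$level_tol_mmHg,
                              smooth_s = pc$smooth_s, hop_s = pc$hop_s)
  }
  stopifnot(inherits(plateau, "icp_plateau"))
  a <- rec$annotations
  fs <- rec$sampling_hz
  n <- length(rec$icp_mmHg)
  icp_b <- mean(rec$icp_mmHg[
    time_window_idx(a$baseline_start_s, a$baseline_end_s, fs, n)])
  icp_p <- mean(rec$icp_mmHg[
    time_window_idx(plateau$start_s, plateau$end_s, fs, n)])
  dp <- icp_p - icp_b
  if (dp <= 0) {
    stopf("plateau mean (%.2f) does not exceed baseline mean (%.2f) mmHg%s",
          icp_p, icp_b, "; check annotations or plateau detection")
  }
  rate <- a$infusion_rate_ml_per_min
  dt_s <- plateau$delta_t_inf_s
  dv <- rate * dt_s / 60
  out <- data.frame(
    icp_b_mmHg = icp_b,
    icp_p_mmHg = icp_p,
    delta_p_inf_mmHg = dp,
    delta_t_inf_s = dt_s,
    delta_v_inf_ml = dv,
    c_inf_ml_per_mmHg = dv / dp,
    rout_mmHg_per_ml_per_min = dp / rate
  )
  class(out) <- c("infusion_metrics", class(out))
  out
}
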