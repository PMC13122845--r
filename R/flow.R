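# Arterial flow curves and the cerebral arterial volume-change amplitude.
#
# The flow side of the physiological compliance estimate: cine phase-contrast
# MRI yields, for each of the three feeding arteries (left/right internal
# carotid, basilar), a flow curve of 32 samples over one reconstructed cardiac
# cycle. Summing the three gives the total arterial inflow Q_ART; integrating
# Q_ART over the cycle gives the arterial volume-change curve V_ART, whose
# max - min amplitude is dV_ART.

VESSELS <- c("ICAL", "ICAR", "BA")
N_FRAMES <- 32L

#' Construct an arterial flow curve
#'
#' Represents one vessel's flow over a single reconstructed cardiac cycle.
#' Clinical flow software exports mL/min; values are converted to mL/s once,
#' here, and kept in mL/s internally. Frame `i` (0-based) sits at time
#' `i * period_s / length(values)`; the cycle is half-open `[0, T)`.
#'
#' @param values Numeric vector of flow samples (one cardiac cycle).
#' @param period_s Cardiac period in seconds (> 0).
#' @param vessel_id Optional vessel label, one of `"ICAL"`, `"ICAR"`, `"BA"`.
#' @param units Units of `values`: `"ml_per_min"` (default, as exported by
#'   clinical flow software) or `"ml_per_s"`.
#' @return An object of class `flow_curve` with fields `values_ml_per_s`,
#'   `period_s`, `vessel_id`.
#' @examples
#' fc <- flow_curve(rep(426, 32), period_s = 0.845)
#' mean_flow_ml_per_min(fc)
#' @export
flow_curve <- function(values, period_s, vessel_id = NA_character_,
                       units = c("ml_per_min", "ml_per_s")) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stopf("flow curve contains non-finite values")
  if (!is.finite(period_s) || period_s <= 0) {
    stopf("cardiac period must be a positive number, got %s", format(period_s))
  }
  v <- if (units == "ml_per_min") values / 60 else values
  structure(
    list(values_ml_per_s = v, period_s = as.numeric(period_s),
         vessel_id = vessel_id),
    class = "flow_curve"
  )
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %s: %d frames, T = %.3f s, mean %.1f mL/min\n",
              ifelse(is.na(x$vessel_id), "?", x$vessel_id),
              length(x$values_ml_per_s), x$period_s,
              mean_flow_ml_per_min(x)))
  invisible(x)
}

#' Mean flow of a curve in mL/min
#'
#' @param q A [flow_curve].
#' @return Mean flow over the cycle, mL/min.
#' @export
mean_flow_ml_per_min <- function(q) {
  stopifnot(inherits(q, "flow_curve"))
  mean(q$values_ml_per_s) * 60
}

#' Total cerebral arterial inflow Q_ART
#'
#' Pointwise sum of the left and right internal carotid and basilar flow
#' curves. The three curves must share the same length and cardiac period.
#' Negative samples (flow-software segmentation normally exports arterial
#' inflow as positive) are kept by default; `clamp_negative = TRUE` zeroes
#' them per vessel before summing.
#'
#' @param ical,icar,ba [flow_curve] objects for the three vessels.
#' @param clamp_negative Zero negative samples per vessel before summing.
#' @return A [flow_curve] for the summed inflow (vessel id `"QART"`).
#' @export
sum_arterial_flows <- function(ical, icar, ba, clamp_negative = FALSE) {
  curves <- list(ical, icar, ba)
  for (q in curves) stopifnot(inherits(q, "flow_curve"))
  len <- vapply(curves, function(q) length(q$values_ml_per_s), integer(1))
  if (length(unique(len)) != 1L) {
    stopf("flow curves have mismatched lengths: %s",
          paste(len, collapse = ", "))
  }
  per <- vapply(curves, function(q) q$period_s, numeric(1))
  if (diff(range(per)) > 1e-9 * max(per)) {
    stopf("flow curves have mismatched cardiac periods: %s s",
          paste(format(per), collapse = ", "))
  }
  vals <- lapply(curves, function(q) {
    v <- q$values_ml_per_s
    if (clamp_negative) pmax(v, 0) else v
  })
  flow_curve(vals[[1]] + vals[[2]] + vals[[3]], period_s = per[1],
             vessel_id = "QART", units = "ml_per_s")
}

#' Arterial volume-change curve V_ART and its amplitude
#'
#' Cumulative trapezoidal integral of the total arterial inflow over one
#' cardiac cycle, with the cycle closed periodically (the final node at
#' `t = T` reuses frame 0), so that for an all-positive flow the full-cycle
#' integral equals mean flow times the period exactly. The amplitude
#' `delta_v_art_ml = max(V) - min(V)` is the cerebral arterial volume change
#' dV_ART. With `subtract_mean = TRUE` the mean flow is removed before
#' integrating, isolating the pulsatile volume component (the alternative
#' convention used when only arterial wall expansion is of interest).
#'
#' @param q A [flow_curve], typically from [sum_arterial_flows()].
#' @param subtract_mean Remove mean flow before integrating (default `FALSE`,
#'   the total-volume convention).
#' @return An object of class `volume_curve` with `values_ml` (33 nodes on
#'   `t = 0, T/32, ..., T`), `times_s`, `delta_v_art_ml`, `subtract_mean`.
#' @examples
#' q <- flow_curve(rep(426, 32), period_s = 0.845)
#' volume_curve(q)$delta_v_art_ml  # (426/60) * 0.845 = 6.0 mL
#' @export
volume_curve <- function(q, subtract_mean = FALSE) {
  stopifnot(inherits(q, "flow_curve"))
  x <- q$values_ml_per_s
  if (!all(is.finite(x))) stopf("flow curve contains non-finite values")
  n <- length(x)
  if (subtract_mean) x <- x - mean(x)
  dt <- q$period_s / n
  xp <- c(x, x[1])                      # periodic closure at t = T
  tt <- seq(0, q$period_s, length.out = n + 1L)
  v <- as.numeric(pracma::cumtrapz(tt, xp))
  structure(
    list(values_ml = v, times_s = tt,
         delta_v_art_ml = max(v) - min(v),
         subtract_mean = subtract_mean, period_s = q$period_s),
    class = "volume_curve"
  )
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf("<volume_curve> T = %.3f s, dV_ART = %.2f mL (%s convention)\n",
              x$period_s, x$delta_v_art_ml,
              if (x$subtract_mean) "mean-subtracted" else "total-volume"))
  invisible(x)
}

#' Amplitude of a volume curve (dV_ART)
#'
#' @param v A [volume_curve].
#' @return `max - min` of the curve, mL (always >= 0).
#' @export
delta_v_art <- function(v) {
  stopifnot(inherits(v, "volume_curve"))
  max(v$values_ml) - min(v$values_ml)
}
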