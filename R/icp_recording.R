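# Container for a lumbar ICP recording with infusion annotations.

#' Construct an ICP recording
#'
#' A uniformly sampled lumbar CSF pressure trace plus the annotations a
#' constant-rate infusion analysis needs: baseline window, infusion start,
#' infusion rate, recording end. Mean lumbar CSF pressure is taken as
#' equivalent to mean intracranial pressure.
#'
#' @param icp_mmHg Numeric vector of pressure samples (mmHg).
#' @param sampling_hz Sampling rate in Hz (> 0).
#' @param annotations Named list with `baseline_start_s`, `baseline_end_s`,
#'   `infusion_start_s`, `infusion_rate_ml_per_min`, `recording_end_s`.
#' @return An object of class `icp_recording`.
#' @export
icp_recording <- function(icp_mmHg, sampling_hz, annotations) {
  icp_mmHg <- as.numeric(icp_mmHg)
  if (length(icp_mmHg) == 0L) stopf("ICP trace is empty")
  if (!all(is.finite(icp_mmHg))) stopf("ICP trace contains non-finite values")
  if (!is.finite(sampling_hz) || sampling_hz <= 0) {
    stopf("sampling rate must be positive, got %s", format(sampling_hz))
  }
  annotations <- validate_annotations(annotations,
                                      span_s = length(icp_mmHg) / sampling_hz)
  structure(
    list(icp_mmHg = icp_mmHg, sampling_hz = as.numeric(sampling_hz),
         annotations = annotations),
    class = "icp_recording"
  )
}

#' @keywords internal
#' @noRd
validate_annotations <- function(ann, span_s) {
  need <- c("baseline_start_s", "baseline_end_s", "infusion_start_s",
            "infusion_rate_ml_per_min", "recording_end_s")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    stopf("annotations missing field(s): %s", paste(missing, collapse = ", "))
  }
  ann <- lapply(ann[need], as.numeric)
  if (!all(vapply(ann, is.finite, logical(1)))) {
    stopf("annotations contain non-finite values")
  }
  if (ann$infusion_rate_ml_per_min <= 0) {
    stopf("infusion rate must be > 0 mL/min, got %g",
          ann$infusion_rate_ml_per_min)
  }
  if (ann$baseline_start_s < 0 || ann$baseline_end_s > span_s + 1e-6 ||
      ann$recording_end_s > span_s + 1e-6) {
    stopf("annotation times fall outside the recorded span [0, %g] s", span_s)
  }
  if (ann$baseline_end_s <= ann$baseline_start_s) {
    stopf("baseline window is empty or reversed")
  }
  if (ann$infusion_start_s < ann$baseline_end_s) {
    stopf("infusion start (%g s) precedes baseline end (%g s)",
          ann$infusion_start_s, ann$baseline_end_s)
  }
  ann
}

#' @export
print.icp_recording <- function(x, ...) {
  a <- x$annotations
  cat(sprintf(paste0(
    "<icp_recording> %.0f s @ %g Hz | baseline [%g, %g] s, infusion at %g s",
    " (%.2g mL/min)\n"),
    length(x$icp_mmHg) / x$sampling_hz, x$sampling_hz,
    a$baseline_start_s, a$baseline_end_s, a$infusion_start_s,
    a$infusion_rate_ml_per_min))
  invisible(x)
}

#' Construct an ICP segment
#'
#' A contiguous slice of an ICP recording used for pulse analysis.
#'
#' @param values_mmHg Numeric pressure samples.
#' @param sampling_hz Sampling rate, Hz.
#' @param origin Which phase the slice comes from.
#' @return An object of class `icp_segment`.
#' @export
icp_segment <- function(values_mmHg, sampling_hz,
                        origin = c("baseline", "infusion", "plateau")) {
  origin <- match.arg(origin)
  values_mmHg <- as.numeric(values_mmHg)
  if (!all(is.finite(values_mmHg))) stopf("segment contains non-finite values")
  structure(
    list(values_mmHg = values_mmHg, sampling_hz = as.numeric(sampling_hz),
         origin = origin),
    class = "icp_segment"
  )
}

#' @export
print.icp_segment <- function(x, ...) {
  cat(sprintf("<icp_segment> %s: %.1f s @ %g Hz, mean %.1f mmHg\n",
              x$origin, length(x$values_mmHg) / x$sampling_hz,
              x$sampling_hz, mean(x$values_mmHg)))
  invisible(x)
}
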