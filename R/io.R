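# On-disk formats: comma-delimited UTF-8 with one header line for traces and
# tables, YAML sidecars for recording annotations. Flow files keep the
# clinical mL/min unit; conversion to mL/s happens once, at load, inside
# flow_curve().

#' Write one vessel flow curve to CSV
#'
#' Columns `vessel_id, cardiac_period_s, frame, flow_ml_per_min`, one row
#' per cardiac frame.
#'
#' @param fc A [flow_curve].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_curve <- function(fc, path) {
  stopifnot(inherits(fc, "flow_curve"))
  n <- length(fc$values_ml_per_s)
  dt <- data.table::data.table(
    vessel_id = fc$vessel_id,
    cardiac_period_s = fc$period_s,
    frame = seq_len(n) - 1L,
    flow_ml_per_min = fc$values_ml_per_s * 60
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read the three arterial flow curves of one subject
#'
#' Expects exactly the three vessels ICAL, ICAR, BA (in any file order),
#' 32 frames each, all sharing one cardiac period. Violations raise named
#' errors identifying the offending file.
#'
#' @param paths Character vector of three CSV paths written by
#'   [write_flow_curve()] (or any file with the same columns).
#' @return Named list of [flow_curve] objects: `ICAL`, `ICAR`, `BA`.
#' @export
read_flow_curves <- function(paths) {
  if (length(paths) != 3L) stopf("expected 3 flow files, got %d",
                                 length(paths))
  curves <- lapply(paths, read_one_flow)
  ids <- vapply(curves, function(q) q$vessel_id, character(1))
  missing <- setdiff(VESSELS, ids)
  if (length(missing)) {
    stopf("missing vessel(s): %s (found %s)",
          paste(missing, collapse = ", "), paste(ids, collapse = ", "))
  }
  names(curves) <- ids
  per <- vapply(curves, function(q) q$period_s, numeric(1))
  if (diff(range(per)) > 1e-9 * max(per)) {
    stopf("cardiac period mismatch across vessels: %s s",
          paste(sprintf("%s=%.4g", ids, per), collapse = ", "))
  }
  curves[VESSELS]
}

#' @keywords internal
#' @noRd
read_one_flow <- function(path) {
  if (!file.exists(path)) stopf("flow file not found: %s", path)
  dt <- data.table::fread(path, colClasses = list(character = "vessel_id"))
  need <- c("vessel_id", "cardiac_period_s", "frame", "flow_ml_per_min")
  if (!all(need %in% names(dt))) {
    stopf("flow file %s lacks column(s): %s", path,
          paste(setdiff(need, names(dt)), collapse = ", "))
  }
  if (!is.numeric(dt$flow_ml_per_min) || anyNA(dt$flow_ml_per_min)) {
    stopf("non-numeric flow values in %s", path)
  }
  if (nrow(dt) != N_FRAMES) {
    stopf("flow file %s has %d frames; expected %d", path, nrow(dt), N_FRAMES)
  }
  vid <- unique(dt$vessel_id)
  if (length(vid) != 1L || !vid %in% VESSELS) {
    stopf("flow file %s must declare one vessel_id in {%s}", path,
          paste(VESSELS, collapse = ", "))
  }
  per <- unique(dt$cardiac_period_s)
  if (length(per) != 1L) stopf("inconsistent cardiac_period_s within %s", path)
  data.table::setorderv(dt, "frame")
  flow_curve(dt$flow_ml_per_min, period_s = per, vessel_id = vid,
             units = "ml_per_min")
}

#' Write an ICP recording to CSV plus a YAML annotation sidecar
#'
#' The trace goes to `path` with columns `time_s, icp_mmHg`; sampling rate
#' and infusion annotations go to `annotation_path` as YAML.
#'
#' @param rec An [icp_recording].
#' @param path Trace CSV path.
#' @param annotation_path YAML sidecar path.
#' @return `path`, invisibly.
#' @export
write_icp_recording <- function(rec, path, annotation_path) {
  stopifnot(inherits(rec, "icp_recording"))
  n <- length(rec$icp_mmHg)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1L) / rec$sampling_hz,
    icp_mmHg = rec$icp_mmHg
  )
  data.table::fwrite(dt, path)
  yaml::write_yaml(c(list(sampling_hz = rec$sampling_hz), rec$annotations),
                   annotation_path)
  invisible(path)
}

#' Read an ICP recording and its annotation sidecar
#'
#' Validates that timestamps are uniform (relative deviation of successive
#' intervals below `tol`), that the annotation fields are present, ordered
#' and inside the recorded span, and that the infusion rate is positive.
#'
#' @param path Trace CSV with columns `time_s, icp_mmHg`.
#' @param annotation_path YAML sidecar written by [write_icp_recording()].
#' @param tol Relative tolerance on timestamp uniformity.
#' @return An [icp_recording].
#' @export
read_icp_recording <- function(path, annotation_path, tol = 1e-3) {
  if (!file.exists(path)) stopf("ICP file not found: %s", path)
  if (!file.exists(annotation_path)) {
    stopf("annotation file not found: %s", annotation_path)
  }
  dt <- data.table::fread(path)
  if (!all(c("time_s", "icp_mmHg") %in% names(dt))) {
    stopf("ICP file %s must have columns time_s, icp_mmHg", path)
  }
  if (nrow(dt) == 0L) stopf("ICP trace in %s is empty", path)
  ann <- yaml::read_yaml(annotation_path)
  if (is.null(ann$sampling_hz)) {
    stopf("annotation file %s lacks sampling_hz", annotation_path)
  }
  fs <- as.numeric(ann$sampling_hz)
  if (nrow(dt) > 1L) {
    dts <- diff(dt$time_s)
    if (any(abs(dts - 1 / fs) > tol / fs)) {
      stopf("non-uniform timestamps in %s (declared %g Hz)", path, fs)
    }
  }
  ann$sampling_hz <- NULL
  icp_recording(dt$icp_mmHg, fs, ann)
}

#' Write per-subject metrics to a delimited report
#'
#' One row per subject, stable column order, full floating-point precision
#' (a re-read reproduces the values).
#'
#' @param metrics A `data.frame` of per-subject metrics (see
#'   [analyze_subject()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subject_report <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  data.table::fwrite(metrics, path)
  invisible(path)
}

#' Read a subject report written by [write_subject_report()]
#'
#' @param path Report CSV path.
#' @return A `data.frame`.
#' @export
read_subject_report <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a cohort manifest
#'
#' @param manifest A `data.frame` with columns `subject_id`, `flow_ical`,
#'   `flow_icar`, `flow_ba`, `icp`, `annotations` and optionally `group`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' Relative file paths are resolved against the manifest's directory.
#' Duplicate subject ids or missing referenced files are errors: a manifest
#' never silently drops a subject.
#'
#' @param path Manifest CSV path.
#' @return A `data.frame` with absolute paths.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- as.data.frame(data.table::fread(path))
  need <- c("subject_id", "flow_ical", "flow_icar", "flow_ba", "icp",
            "annotations")
  if (!all(need %in% names(m))) {
    stopf("manifest lacks column(s): %s",
          paste(setdiff(need, names(m)), collapse = ", "))
  }
  if (anyDuplicated(m$subject_id)) {
    stopf("duplicate subject_id(s): %s",
          paste(unique(m$subject_id[duplicated(m$subject_id)]),
                collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (col in c("flow_ical", "flow_icar", "flow_ba", "icp", "annotations")) {
    p <- m[[col]]
    rel <- !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(base, p[rel])
    missing <- !file.exists(p)
    if (any(missing)) {
      stopf("manifest references missing file(s): %s",
            paste(p[missing], collapse = ", "))
    }
    m[[col]] <- p
  }
  m
}
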