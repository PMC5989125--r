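#' Write / read a recording as text + JSON sidecar
#'
#' A recording is stored as two files: `<stem>_samples.txt` (one column
#' of amplitudes, uV) and `<stem>.json` (sidecar with
#' `sampling_rate_hz`, `event_times_ms`, `channel_label`, `units` and any
#' metadata). Text-first so fixtures are diffable; round trips are
#' bit-identical at full double precision.
#'
#' @param recording a [vep_recording()].
#' @param stem output path stem (directory must exist).
#' @return `write_recording` returns the sidecar path invisibly;
#'   `read_recording` returns a [vep_recording()].
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "vep_recording"))
  # %.17g guarantees an exact double round trip (fwrite/JSON do not)
  writeLines(sprintf("%.17g", recording$samples),
             paste0(stem, "_samples.txt"))
  sidecar <- list(units = "uV",
                  sampling_rate_hz = recording$sampling_rate_hz,
                  event_times_ms = sprintf("%.17g", recording$event_times_ms),
                  channel_label = recording$channel_label,
                  meta = recording$meta)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".json"))
}

require_keys <- function(sidecar, keys, path) {
  missing <- setdiff(keys, names(sidecar))
  if (length(missing))
    stopf("sidecar %s is missing key(s): %s", path,
          paste(missing, collapse = ", "))
}

check_units <- function(sidecar, path) {
  if (!is.null(sidecar$units) &&
      !sidecar$units %in% c("uV", "µV", "microvolt", "microvolts"))
    stopf("sidecar %s declares units '%s'; only microvolts are supported (no silent conversion)",
          path, sidecar$units)
}

#' @rdname write_recording
#' @param stem path stem used when writing.
#' @export
read_recording <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  require_keys(sidecar, c("sampling_rate_hz", "event_times_ms"), sidecar_path)
  check_units(sidecar, sidecar_path)
  samples <- data.table::fread(paste0(stem, "_samples.txt"),
                               header = FALSE)[[1]]
  vep_recording(samples, sidecar$sampling_rate_hz,
                as.numeric(unlist(sidecar$event_times_ms)),
                channel_label = sidecar$channel_label %||% "Oz-Fz",
                meta = as.list(sidecar$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an epoch set as text + JSON sidecar
#'
#' Epochs are stored as a tab-delimited matrix `<stem>_epochs.tsv`
#' (rows = epochs) and a JSON sidecar `<stem>.json` carrying
#' `time_axis_ms`, `kept_mask`, `units` and provenance metadata.
#'
#' @param epochs a [vep_epochs()].
#' @param stem output path stem.
#' @return `write_epochs` returns the sidecar path invisibly;
#'   `read_epochs` returns a [vep_epochs()].
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "vep_epochs"))
  data.table::fwrite(data.table::as.data.table(epochs$data),
                     paste0(stem, "_epochs.tsv"), sep = "\t",
                     col.names = FALSE)
  meta <- epochs$meta
  meta$rejection_report <- if (!is.null(meta$rejection_report))
    unclass(meta$rejection_report)
  sidecar <- list(units = "uV", time_axis_ms = epochs$time_axis_ms,
                  kept_mask = epochs$kept_mask,
                  sampling_rate_hz = epochs$sampling_rate_hz, meta = meta)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".json"))
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  require_keys(sidecar, c("time_axis_ms", "kept_mask"), sidecar_path)
  check_units(sidecar, sidecar_path)
  data <- as.matrix(data.table::fread(paste0(stem, "_epochs.tsv"),
                                      header = FALSE, sep = "\t"))
  dimnames(data) <- NULL
  meta <- as.list(sidecar$meta)
  if (!is.null(meta$rejection_report))
    meta$rejection_report <- structure(meta$rejection_report,
                                       class = "rejection_report")
  vep_epochs(data, as.numeric(sidecar$time_axis_ms),
             kept_mask = as.logical(sidecar$kept_mask),
             sampling_rate_hz = sidecar$sampling_rate_hz, meta = meta)
}

#' Per-subject results table of a processed cohort
#'
#' Flattens a list of per-subject measurements (as produced by
#' [measure_subject()] / [run_pipeline()]) into the cohort-level table
#' used for group statistics.
#'
#' @param results list of per-subject result lists.
#' @return data.frame with columns `subject_id`, `group`, `st_vep_uV`,
#'   `n_epochs_used`, `n1_latency_ms`, `n1_uV`, `p1_latency_ms`, `p1_uV`,
#'   `n1p1_uV`, `rejected_fraction`.
#' @export
cohort_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(subject_id = r$st$subject_id, group = r$st$group,
               st_vep_uV = r$st$st_vep_uV,
               n_epochs_used = r$st$n_epochs_used,
               n1_latency_ms = r$conv$n1$latency_ms,
               n1_uV = r$conv$n1$amplitude_uV,
               p1_latency_ms = r$conv$p1$latency_ms,
               p1_uV = r$conv$p1$amplitude_uV,
               n1p1_uV = r$conv$n1p1_uV,
               rejected_fraction = r$rejected_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
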