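#' Continuous single-channel EEG recording
#'
#' Container for a continuous occipital EEG trace (conventionally Oz
#' referenced to Fz) together with its sampling rate and the stimulus
#' (pattern-reversal) onset times. All amplitudes are in microvolts and
#' all times in milliseconds.
#'
#' @param samples numeric vector of sample amplitudes (uV).
#' @param sampling_rate_hz sampling rate (Hz), > 0.
#' @param event_times_ms strictly increasing stimulus onset times (ms),
#'   all inside the recording.
#' @param channel_label montage label, e.g. `"Oz-Fz"`.
#' @param meta optional named list of free-form metadata (subject id,
#'   group, seed, stimulus parameters ...), carried through serialization.
#' @return An object of class `vep_recording`.
#' @export
vep_recording <- function(samples, sampling_rate_hz,
                          event_times_ms = numeric(0),
                          channel_label = "Oz-Fz", meta = list()) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stopf("'samples' must be a nonempty numeric vector")
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz")
  if (sampling_rate_hz <= 0) stopf("'sampling_rate_hz' must be > 0")
  event_times_ms <- as.numeric(event_times_ms)
  if (length(event_times_ms)) {
    if (any(diff(event_times_ms) <= 0))
      stopf("event times must be strictly increasing")
    dur_ms <- length(samples) / sampling_rate_hz * 1000
    if (min(event_times_ms) < 0 || max(event_times_ms) >= dur_ms)
      stopf("event times must lie inside the recording [0, %.1f ms)", dur_ms)
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 event_times_ms = event_times_ms,
                 channel_label = channel_label,
                 meta = meta),
            class = "vep_recording")
}

#' @export
print.vep_recording <- function(x, ...) {
  cat(sprintf("<vep_recording> %s: %d samples @ %g Hz (%.2f s), %d events\n",
              x$channel_label, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz,
              length(x$event_times_ms)))
  invisible(x)
}

#' Set of stimulus-locked epochs
#'
#' An epochs-by-samples matrix cut from a continuous recording, with a
#' shared time axis (ms post-stimulus) and a per-epoch kept/rejected mask.
#' Units are fixed to microvolts.
#'
#' @param data numeric matrix, one row per epoch.
#' @param time_axis_ms per-column times from stimulus onset (ms), uniform.
#' @param kept_mask logical vector, one flag per epoch (`TRUE` = kept).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param meta optional named list of provenance metadata.
#' @return An object of class `vep_epochs`.
#' @export
vep_epochs <- function(data, time_axis_ms, kept_mask = NULL,
                       sampling_rate_hz = NULL, meta = list()) {
  data <- as.matrix(data)
  if (ncol(data) != length(time_axis_ms))
    stopf("time axis length (%d) != number of samples per epoch (%d)",
          length(time_axis_ms), ncol(data))
  if (ncol(data) >= 2) {
    dt <- diff(time_axis_ms)
    if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
      stopf("time axis must be uniform")
    if (is.null(sampling_rate_hz)) sampling_rate_hz <- 1000 / dt[1]
  }
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, nrow(data))
  if (length(kept_mask) != nrow(data))
    stopf("kept_mask length (%d) != number of epochs (%d)",
          length(kept_mask), nrow(data))
  structure(list(data = data, time_axis_ms = as.numeric(time_axis_ms),
                 kept_mask = as.logical(kept_mask), units = "µV",
                 sampling_rate_hz = sampling_rate_hz, meta = meta),
            class = "vep_epochs")
}

#' @export
print.vep_epochs <- function(x, ...) {
  cat(sprintf("<vep_epochs> %d epochs x %d samples (%g-%g ms), %d kept\n",
              nrow(x$data), ncol(x$data), min(x$time_axis_ms),
              max(x$time_axis_ms), sum(x$kept_mask)))
  invisible(x)
}

#' Number of epochs / kept epochs in an epoch set
#' @param x a `vep_epochs` object.
#' @return Integer count.
#' @export
n_epochs <- function(x) nrow(x$data)

#' @rdname n_epochs
#' @export
n_kept <- function(x) sum(x$kept_mask)

#' Extract the kept-epoch submatrix
#' @param x a `vep_epochs` object.
#' @return Numeric matrix of kept epochs (rows) by samples (columns).
#' @export
kept_data <- function(x) x$data[x$kept_mask, , drop = FALSE]
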