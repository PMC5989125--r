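#' Signed mean amplitude of one epoch
#'
#' The single-trial statistic's building block: the arithmetic mean of
#' every sample in the epoch. Unlike peak measures, the mean of a
#' transient deflection does not depend on where in the epoch it occurs,
#' so trial-to-trial latency jitter leaves it untouched. The signed mean
#' is the documented default; `mode = "rectified"` (mean absolute
#' voltage) exists as a sensitivity-analysis variant.
#'
#' @param epoch numeric vector of sample amplitudes (uV), nonempty.
#' @param mode `"signed"` (default) or `"rectified"`.
#' @return Mean amplitude (uV).
#' @export
epoch_mean <- function(epoch, mode = c("signed", "rectified")) {
  mode <- match.arg(mode)
  if (length(epoch) == 0L) stopf("empty epoch")
  if (mode == "signed") mean(epoch) else mean(abs(epoch))
}

#' Single-trial VEP amplitude of a subject
#'
#' Computes the signed mean amplitude of every kept (un-artifacted) epoch
#' and their grand average — the per-subject single-trial VEP (st-VEP)
#' amplitude. Rejected epochs are excluded from both the per-epoch vector
#' and the grand average. Algebraically the grand average equals the
#' signed mean of the point-by-point averaged waveform over the same
#' epochs: the statistic differs from conventional readouts in *what* is
#' measured (signed mean vs peak-to-peak), not in averaging order.
#'
#' @param epochs a [vep_epochs()] with at least one kept epoch.
#' @param subject_id,group identifiers carried into the result.
#' @param mode amplitude mode, see [epoch_mean()].
#' @return A `subject_result`: `subject_id`, `group`, `epoch_means_uV`
#'   (kept epochs), `st_vep_uV`, `n_epochs_used`, `rejection` (the
#'   rejection report if one was attached by [reject_artifacts()]).
#' @export
st_vep <- function(epochs, subject_id = "subject", group = NA_character_,
                   mode = c("signed", "rectified")) {
  stopifnot(inherits(epochs, "vep_epochs"))
  mode <- match.arg(mode)
  if (n_kept(epochs) < 1)
    stopf("all epochs rejected for subject '%s'", subject_id)
  kd <- kept_data(epochs)
  means <- if (mode == "signed") rowMeans(kd) else rowMeans(abs(kd))
  structure(list(subject_id = subject_id, group = group,
                 epoch_means_uV = means,
                 st_vep_uV = sum(means) / length(means),
                 n_epochs_used = length(means),
                 rejection = epochs$meta$rejection_report),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s%s: st-VEP %.3f uV over %d epochs\n",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              x$st_vep_uV, x$n_epochs_used))
  invisible(x)
}

#' Stacked single-trial image
#'
#' Data backing an ERP-image display: kept trials as rows against time,
#' optionally sorted by their signed mean and smoothed with a boxcar over
#' adjacent trials. Stacking color-coded trials makes responses visible
#' that no individual trace shows. Pure data export; rendering (e.g.
#' `image()` or a heatmap) is left to the caller.
#'
#' Smoothing: output row i is the mean of `smooth_trials` consecutive
#' input rows centered on i (window shifted inward at the edges so every
#' output row averages exactly `smooth_trials` rows). `smooth_trials`
#' equal to the number of kept trials reproduces the conventional average
#' in every row; 1 is the identity.
#'
#' @param epochs a [vep_epochs()].
#' @param sort_key `"none"` (recording order) or `"epoch_mean"`
#'   (ascending signed mean).
#' @param smooth_trials boxcar width in trials (default 1 = none).
#' @return Numeric matrix, kept trials x samples (uV), with the time axis
#'   as attribute `"time_axis_ms"`.
#' @export
erp_image <- function(epochs, sort_key = c("none", "epoch_mean"),
                      smooth_trials = 1L) {
  stopifnot(inherits(epochs, "vep_epochs"))
  sort_key <- match.arg(sort_key)
  kd <- kept_data(epochs)
  n <- nrow(kd)
  if (n < 1) stopf("no kept epochs")
  if (smooth_trials > n)
    stopf("smooth_trials (%d) exceeds the number of kept epochs (%d)",
          smooth_trials, n)
  if (sort_key == "epoch_mean") kd <- kd[order(rowMeans(kd)), , drop = FALSE]
  if (smooth_trials > 1L) {
    s <- as.integer(smooth_trials)
    starts <- pmin(pmax(seq_len(n) - (s - 1L) %/% 2L, 1L), n - s + 1L)
    cs <- rbind(0, apply(kd, 2L, cumsum))
    kd <- (cs[starts + s, , drop = FALSE] - cs[starts, , drop = FALSE]) / s
  }
  attr(kd, "time_axis_ms") <- epochs$time_axis_ms
  kd
}
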