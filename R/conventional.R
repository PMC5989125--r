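#' Averaged VEP waveform
#'
#' Point-by-point mean over the kept epochs — the classic transient VEP.
#' Phase-locked activity survives; activity whose phase or latency varies
#' across trials cancels toward zero as 1/sqrt(n).
#'
#' @param epochs a [vep_epochs()] with at least one kept epoch.
#' @return A `vep_waveform`: list with `samples` (uV) and `time_axis_ms`.
#' @export
average_waveform <- function(epochs) {
  stopifnot(inherits(epochs, "vep_epochs"))
  if (n_kept(epochs) < 1) stopf("no kept epochs to average")
  structure(list(samples = colMeans(kept_data(epochs)),
                 time_axis_ms = epochs$time_axis_ms),
            class = "vep_waveform")
}

#' @export
print.vep_waveform <- function(x, ...) {
  cat(sprintf("<vep_waveform> %d samples, %g-%g ms, range [%.2f, %.2f] uV\n",
              length(x$samples), min(x$time_axis_ms), max(x$time_axis_ms),
              min(x$samples), max(x$samples)))
  invisible(x)
}

# Closed-window extremum with earliest-sample tie-break. Window edges are
# mapped to the nearest sample. Returns a peak_result.
window_extremum <- function(waveform, window_ms, label, which = c("min", "max")) {
  which <- match.arg(which)
  t <- waveform$time_axis_ms
  if (window_ms[1] < min(t) - 1e-9 || window_ms[2] > max(t) + 1e-9)
    stopf("%s search window [%g, %g] ms not covered by waveform [%g, %g] ms",
          label, window_ms[1], window_ms[2], min(t), max(t))
  dt <- t[2] - t[1]
  idx <- which(t >= window_ms[1] - dt / 2 & t <= window_ms[2] + dt / 2)
  v <- waveform$samples[idx]
  j <- if (which == "min") which.min(v) else which.max(v)  # earliest tie wins
  structure(list(label = label, latency_ms = t[idx[j]],
                 amplitude_uV = v[j], search_window_ms = window_ms,
                 at_edge = j == 1L || j == length(v)),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak> %s: %.2f uV at %.1f ms (window %g-%g ms)%s\n",
              x$label, x$amplitude_uV, x$latency_ms, x$search_window_ms[1],
              x$search_window_ms[2], if (x$at_edge) " [edge]" else ""))
  invisible(x)
}

#' Locate the N1 peak
#'
#' The most negative point of the averaged waveform in the closed
#' 60-90 ms window (earliest sample wins ties). Window-edge hits are
#' flagged in the result (`at_edge`).
#'
#' @param waveform a `vep_waveform` covering the search window.
#' @param window_ms search window (ms), default `c(60, 90)`.
#' @return A `peak_result`.
#' @export
find_n1 <- function(waveform, window_ms = c(60, 90)) {
  window_extremum(waveform, window_ms, "N1", "min")
}

#' Locate the P1 peak
#'
#' The most positive point following N1: the search window is
#' `[max(window_ms[1], n1 latency), window_ms[2]]`, default 80-120 ms.
#'
#' @param waveform a `vep_waveform`.
#' @param n1 the `peak_result` returned by [find_n1()].
#' @param window_ms nominal search window (ms), default `c(80, 120)`.
#' @return A `peak_result`.
#' @export
find_p1 <- function(waveform, n1, window_ms = c(80, 120)) {
  lo <- max(window_ms[1], n1$latency_ms)
  if (lo > window_ms[2])
    stopf("P1 window is empty: N1 latency %.1f ms exceeds %g ms",
          n1$latency_ms, window_ms[2])
  window_extremum(waveform, c(lo, window_ms[2]), "P1", "max")
}

#' N1-P1 peak-to-peak amplitude
#'
#' @param result a `conventional_result` (or any list with `n1` and `p1`
#'   peak results).
#' @return P1 amplitude minus N1 amplitude (uV).
#' @export
n1p1_amplitude <- function(result) {
  result$p1$amplitude_uV - result$n1$amplitude_uV
}

#' Conventional transient VEP analysis
#'
#' Averages the kept epochs point-by-point and measures the N1 (most
#' negative point, 60-90 ms) and P1 (most positive point following N1,
#' 80-120 ms) peaks and their peak-to-peak amplitude.
#'
#' @param epochs a [vep_epochs()].
#' @param peak_windows list with elements `n1` and `p1` (ms windows).
#' @return A `conventional_result`: `waveform`, `n1`, `p1`, `n1p1_uV`.
#' @export
conventional_vep <- function(epochs,
                             peak_windows = list(n1 = c(60, 90),
                                                 p1 = c(80, 120))) {
  wf <- average_waveform(epochs)
  n1 <- find_n1(wf, peak_windows$n1)
  p1 <- find_p1(wf, n1, peak_windows$p1)
  structure(list(waveform = wf, n1 = n1, p1 = p1,
                 n1p1_uV = p1$amplitude_uV - n1$amplitude_uV,
                 n_epochs_used = n_kept(epochs)),
            class = "conventional_result")
}

#' @export
print.conventional_result <- function(x, ...) {
  cat(sprintf(
    "<conventional_result> N1 %.2f uV @ %.1f ms, P1 %.2f uV @ %.1f ms, N1-P1 %.2f uV (%d epochs)\n",
    x$n1$amplitude_uV, x$n1$latency_ms, x$p1$amplitude_uV, x$p1$latency_ms,
    x$n1p1_uV, x$n_epochs_used))
  invisible(x)
}
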