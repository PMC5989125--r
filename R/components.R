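#' Specify a stimulus-locked signal component
#'
#' Describes one elementary ingredient of a simulated post-stimulus sweep:
#'
#' * `evoked_biphasic` — a phase-locked negative Gaussian lobe (N1) followed
#'   by a positive Gaussian lobe (P1), identical in every trial; the
#'   component conventional averaging measures.
#' * `induced_monophasic` — a single positive Gaussian deflection whose
#'   per-trial peak latency is drawn from
#'   Normal(`peak_latency_ms`, `latency_jitter_sd_ms`); its signed epoch
#'   mean is latency-invariant, so it survives the single-trial statistic
#'   while averaging smears it out.
#' * `oscillatory` — a windowed sinusoid with fixed or random-per-trial
#'   phase (used by the seven-trial averaging demonstration).
#'
#' @param kind one of `"evoked_biphasic"`, `"induced_monophasic"`,
#'   `"oscillatory"`.
#' @param peak_latency_ms peak latency (ms >= 0). For the biphasic complex
#'   this is the P1 lobe latency.
#' @param amplitude_uV signed peak amplitude (uV). For the biphasic complex
#'   this is the P1 lobe amplitude.
#' @param width_ms Gaussian envelope sigma (ms, > 0).
#' @param latency_jitter_sd_ms SD of per-trial latency jitter (ms, >= 0);
#'   meaningful for `induced_monophasic`.
#' @param n1_latency_ms,n1_amplitude_uV N1 lobe of the biphasic complex
#'   (defaults 75 ms and `-amplitude_uV`, giving equal-area lobes and hence
#'   a near-zero signed epoch mean).
#' @param freq_hz,phase,support_ms oscillatory parameters: frequency (Hz),
#'   `"fixed"` or `"random"` per-trial phase, and the Hann-envelope support
#'   window (ms).
#' @return A `component_spec` list.
#' @export
component_spec <- function(kind = c("evoked_biphasic", "induced_monophasic",
                                    "oscillatory"),
                           peak_latency_ms = 100, amplitude_uV = 3,
                           width_ms = 8, latency_jitter_sd_ms = 0,
                           n1_latency_ms = 75, n1_amplitude_uV = -amplitude_uV,
                           freq_hz = 10, phase = c("fixed", "random"),
                           support_ms = c(200, 400)) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  assert_scalar_num(peak_latency_ms, "peak_latency_ms")
  assert_scalar_num(amplitude_uV, "amplitude_uV")
  assert_scalar_num(width_ms, "width_ms")
  if (peak_latency_ms < 0) stopf("'peak_latency_ms' must be >= 0")
  if (width_ms <= 0) stopf("'width_ms' must be > 0")
  if (latency_jitter_sd_ms < 0) stopf("'latency_jitter_sd_ms' must be >= 0")
  if (kind == "oscillatory" && freq_hz <= 0) stopf("'freq_hz' must be > 0")
  structure(list(kind = kind, peak_latency_ms = peak_latency_ms,
                 amplitude_uV = amplitude_uV, width_ms = width_ms,
                 latency_jitter_sd_ms = latency_jitter_sd_ms,
                 n1_latency_ms = n1_latency_ms,
                 n1_amplitude_uV = n1_amplitude_uV,
                 freq_hz = freq_hz, phase = phase,
                 support_ms = support_ms),
            class = "component_spec")
}

gauss_bump <- function(time_axis_ms, latency_ms, amplitude_uV, width_ms) {
  amplitude_uV * exp(-0.5 * ((time_axis_ms - latency_ms) / width_ms)^2)
}

check_latency_covered <- function(latency_ms, time_axis_ms) {
  if (latency_ms < min(time_axis_ms) || latency_ms > max(time_axis_ms))
    stopf("component latency %.1f ms lies outside the time axis [%.1f, %.1f] ms",
          latency_ms, min(time_axis_ms), max(time_axis_ms))
}

#' Phase-locked biphasic N1-P1 complex
#'
#' Evaluates the synchronized biphasic complex (negative N1 lobe plus
#' positive P1 lobe, both Gaussian) on a sample time axis. Deterministic:
#' the complex is identical in every trial, so pointwise averaging
#' preserves it and its peak-to-peak amplitude is the conventional VEP
#' readout. With equal-area lobes the signed epoch mean is ~0, so the
#' complex is invisible to the single-trial statistic by design.
#'
#' @param spec a `component_spec` of kind `"evoked_biphasic"`.
#' @param time_axis_ms uniform sample times (ms).
#' @return Numeric vector of sample amplitudes (uV).
#' @export
make_evoked_biphasic <- function(spec, time_axis_ms) {
  stopifnot(inherits(spec, "component_spec"), spec$kind == "evoked_biphasic")
  if (spec$amplitude_uV == 0 && spec$n1_amplitude_uV == 0)
    return(numeric(length(time_axis_ms)))
  check_latency_covered(spec$n1_latency_ms, time_axis_ms)
  check_latency_covered(spec$peak_latency_ms, time_axis_ms)
  gauss_bump(time_axis_ms, spec$n1_latency_ms, spec$n1_amplitude_uV,
             spec$width_ms) +
    gauss_bump(time_axis_ms, spec$peak_latency_ms, spec$amplitude_uV,
               spec$width_ms)
}

#' Latency-jittered induced monophasic deflection
#'
#' Evaluates one positive Gaussian deflection whose peak latency is either
#' supplied (`latency_ms`) or drawn from
#' Normal(`peak_latency_ms`, `latency_jitter_sd_ms`) using the current RNG
#' stream. The bump's signed epoch mean,
#' `amplitude_uV * width_ms * sqrt(2*pi) / epoch_duration`, does not depend
#' on where in the epoch it lands (up to edge truncation), which is the
#' mechanism by which latency-jittered induced activity survives the
#' single-trial mean while vanishing from the trial average.
#'
#' If the drawn latency places more than 1% of the bump's mass outside the
#' time axis, a warning is issued (mass is truncated, slightly biasing the
#' epoch mean).
#'
#' @param spec a `component_spec` of kind `"induced_monophasic"`.
#' @param time_axis_ms uniform sample times (ms).
#' @param latency_ms optional fixed latency override (ms); when `NULL`
#'   the latency is drawn from the jitter distribution.
#' @param warn warn on >1% edge truncation (default `TRUE`).
#' @return Numeric vector of sample amplitudes (uV), with the drawn
#'   latency attached as attribute `"latency_ms"`.
#' @export
make_induced_monophasic <- function(spec, time_axis_ms, latency_ms = NULL,
                                    warn = TRUE) {
  stopifnot(inherits(spec, "component_spec"),
            spec$kind == "induced_monophasic")
  check_latency_covered(spec$peak_latency_ms, time_axis_ms)
  if (is.null(latency_ms)) {
    latency_ms <- if (spec$latency_jitter_sd_ms > 0) {
      stats::rnorm(1, spec$peak_latency_ms, spec$latency_jitter_sd_ms)
    } else spec$peak_latency_ms
  }
  lo <- min(time_axis_ms); hi <- max(time_axis_ms)
  outside <- stats::pnorm(lo, latency_ms, spec$width_ms) +
    stats::pnorm(hi, latency_ms, spec$width_ms, lower.tail = FALSE)
  if (warn && outside > 0.01)
    warnf("induced bump at %.1f ms leaves %.1f%% of its mass outside [%g, %g] ms",
          latency_ms, 100 * outside, lo, hi)
  out <- gauss_bump(time_axis_ms, latency_ms, spec$amplitude_uV, spec$width_ms)
  attr(out, "latency_ms") <- latency_ms
  out
}

#' Windowed oscillatory component
#'
#' A sinusoid at `freq_hz` under a Hann envelope confined to
#' `support_ms`, with phase either fixed across trials or drawn uniformly
#' per call. Used by [simulate_fig1_demo()] to contrast synchronized and
#' unsynchronized stimulus-induced activity under averaging.
#'
#' @inheritParams make_induced_monophasic
#' @param spec a `component_spec` of kind `"oscillatory"`.
#' @param phase_rad optional fixed phase override (radians).
#' @return Numeric vector of sample amplitudes (uV) with attribute
#'   `"phase_rad"`.
#' @export
make_oscillatory <- function(spec, time_axis_ms, phase_rad = NULL) {
  stopifnot(inherits(spec, "component_spec"), spec$kind == "oscillatory")
  if (is.null(phase_rad)) {
    phase_rad <- if (spec$phase == "random") stats::runif(1, 0, 2 * pi) else 0
  }
  lo <- spec$support_ms[1]; hi <- spec$support_ms[2]
  env <- numeric(length(time_axis_ms))
  inside <- time_axis_ms >= lo & time_axis_ms <= hi
  env[inside] <- sin(pi * (time_axis_ms[inside] - lo) / (hi - lo))^2
  out <- spec$amplitude_uV * env *
    sin(2 * pi * spec$freq_hz * time_axis_ms / 1000 + phase_rad)
  attr(out, "phase_rad") <- phase_rad
  out
}

#' Induced amplitude needed for a target epoch mean
#'
#' Inverts the mean-contribution formula of the induced monophasic bump:
#' a Gaussian deflection of amplitude A and envelope sigma w contributes
#' `A * w * sqrt(2*pi) / T` to the signed mean of an epoch of duration T,
#' wherever its peak lands. Returns the amplitude realizing a target
#' single-epoch mean.
#'
#' Note this is the *single-epoch* closed form; designing a target that
#' survives the full preprocessing chain (which removes the epoch-locked
#' DC component) additionally requires the baseline compensation performed
#' by [simulate_subject()].
#'
#' @param target_mean_uV desired signed epoch mean (uV).
#' @param width_ms Gaussian envelope sigma (ms, > 0).
#' @param epoch_duration_ms epoch duration (ms, > 0).
#' @return Amplitude in uV.
#' @export
#' @examples
#' calibrate_induced_amplitude(0.824, 20, 250)  # ~4.109 uV
calibrate_induced_amplitude <- function(target_mean_uV, width_ms,
                                        epoch_duration_ms) {
  assert_scalar_num(target_mean_uV, "target_mean_uV")
  if (!is.numeric(width_ms) || width_ms <= 0)
    stopf("'width_ms' must be > 0")
  if (!is.numeric(epoch_duration_ms) || epoch_duration_ms <= 0)
    stopf("'epoch_duration_ms' must be > 0")
  target_mean_uV * epoch_duration_ms / (width_ms * sqrt(2 * pi))
}
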