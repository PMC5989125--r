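#' Specify one simulated subject
#'
#' Parameters of a single simulated pattern-reversal VEP session:
#' `n_epochs` consecutive stimulus-locked sweeps recorded continuously at
#' `sampling_rate_hz`, one reversal every `isi_ms` (default the 3.1
#' reversals/s protocol, i.e. 322.58 ms, leaving a ~72.6 ms unanalyzed
#' gap after each 250 ms sweep). Each sweep carries a phase-locked
#' biphasic N1-P1 complex, a latency-jittered induced monophasic
#' deflection near 100 ms, i.i.d. Gaussian background noise, and a small
#' fraction of whole-epoch high-amplitude artifacts.
#'
#' `target_st_vep_uV` is the *designed observable*: the signed epoch-mean
#' amplitude the subject should exhibit after the full preprocessing
#' chain (DC subtraction + 1 Hz high-pass remove the epoch-locked DC, so
#' the raw induced amplitude must exceed the naive single-epoch
#' calibration; [simulate_subject()] solves for it exactly). Similarly
#' `n1p1_design_uV`, when given, is the designed noise-free averaged
#' N1-P1 peak-to-peak amplitude.
#'
#' @param n_epochs number of sweeps (>= 1), default 600.
#' @param epoch_duration_ms sweep length (ms), default 250; must give an
#'   integer sample count.
#' @param sampling_rate_hz sampling rate (Hz), default 5000.
#' @param isi_ms stimulus period (ms), default `1000 / 3.1`; must be >=
#'   `epoch_duration_ms`. With no gap (`isi_ms == epoch_duration_ms`) a
#'   nonzero st-VEP target is unrealizable: the epoch-locked mean then IS
#'   the recording's DC and preprocessing removes it entirely.
#' @param evoked,induced [component_spec()]s for the two signal
#'   components (pass `NULL` to omit one).
#' @param noise_sd_uV white-noise SD per sample (uV), default 20 (about
#'   4 uV RMS inside the 1-100 Hz band at 5 kHz — low-noise needle
#'   electrodes; single-trial responses stay invisible to the eye).
#' @param artifact_fraction fraction of epochs scaled up as artifacts
#'   (default 0.02, < 0.5).
#' @param artifact_gain whole-epoch amplitude multiplier (> 1, default 10).
#' @param target_st_vep_uV designed post-pipeline st-VEP (uV); `NA` keeps
#'   the induced component's own amplitude.
#' @param n1p1_design_uV designed noise-free averaged N1-P1 (uV); `NA`
#'   keeps the evoked component's own amplitudes (about 6 uV).
#' @param seed integer RNG seed.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(n_epochs = 600, epoch_duration_ms = 250,
                         sampling_rate_hz = 5000, isi_ms = 1000 / 3.1,
                         evoked = component_spec("evoked_biphasic",
                                                 peak_latency_ms = 100,
                                                 amplitude_uV = 3,
                                                 width_ms = 8,
                                                 n1_latency_ms = 75,
                                                 n1_amplitude_uV = -3),
                         induced = component_spec("induced_monophasic",
                                                  peak_latency_ms = 100,
                                                  amplitude_uV = 4.109,
                                                  width_ms = 20,
                                                  latency_jitter_sd_ms = 50),
                         noise_sd_uV = 20, artifact_fraction = 0.02,
                         artifact_gain = 10, target_st_vep_uV = NA_real_,
                         n1p1_design_uV = NA_real_, seed = 1L) {
  if (n_epochs < 1) stopf("'n_epochs' must be >= 1")
  n_samp <- epoch_duration_ms * sampling_rate_hz / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stopf("epoch_duration_ms x sampling_rate_hz must give an integer sample count")
  if (isi_ms < epoch_duration_ms)
    stopf("'isi_ms' (%g) must be >= 'epoch_duration_ms' (%g)",
          isi_ms, epoch_duration_ms)
  if (noise_sd_uV < 0) stopf("'noise_sd_uV' must be >= 0")
  if (artifact_fraction < 0 || artifact_fraction >= 0.5)
    stopf("'artifact_fraction' must be in [0, 0.5)")
  if (artifact_gain <= 1) stopf("'artifact_gain' must be > 1")
  structure(list(n_epochs = as.integer(n_epochs),
                 epoch_duration_ms = epoch_duration_ms,
                 sampling_rate_hz = sampling_rate_hz, isi_ms = isi_ms,
                 evoked = evoked, induced = induced,
                 noise_sd_uV = noise_sd_uV,
                 artifact_fraction = artifact_fraction,
                 artifact_gain = artifact_gain,
                 target_st_vep_uV = target_st_vep_uV,
                 n1p1_design_uV = n1p1_design_uV,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

# Per-epoch means and epoch matrix of a raw sample vector pushed through
# the deterministic part of the preprocessing chain (DC + band-pass +
# epoching; no rejection). Used for noise-free calibration.
unit_pipeline_stats <- function(samples, fs, events_ms, window_ms, filter) {
  rec <- vep_recording(samples, fs, events_ms)
  rec <- dc_subtract(rec)
  rec <- bandpass(rec, filter$low_hz, filter$high_hz, filter$order)
  ep <- suppressWarnings(extract_epochs(rec, window_ms))
  list(means = rowMeans(ep$data), data = ep$data,
       time_axis_ms = ep$time_axis_ms)
}

# The 2-SD kept set of a vector of epoch means (mirrors reject_artifacts).
kept_set <- function(ebar, k) {
  s <- stats::sd(ebar)
  if (s == 0) rep(TRUE, length(ebar)) else abs(ebar - mean(ebar)) <= k * s
}

#' Simulate one subject's continuous recording
#'
#' Generates the continuous single-channel recording of a simulated
#' session: per-sweep evoked and induced components placed at each
#' stimulus onset (induced latencies drawn per trial), i.i.d. Gaussian
#' noise, and whole-epoch artifact scaling. When `target_st_vep_uV`
#' and/or `n1p1_design_uV` are set, the component amplitudes are
#' calibrated *exactly* against the noise-free signal pushed through the
#' same preprocessing chain the analysis will apply (`config`): the
#' induced amplitude is solved linearly so the noise-free post-pipeline
#' st-VEP equals the target (this compensates both the epoch-locked DC
#' removed by the high-pass and any jitter edge truncation), and the
#' evoked scale is solved by root finding so the noise-free averaged
#' N1-P1 equals its design value.
#'
#' Fully reproducible: identical spec (including seed) gives bit-identical
#' output.
#'
#' @param spec a [subject_spec()].
#' @param config the analysis [pipeline_config()] the design targets are
#'   defined against; defaults to the standard chain at the spec's
#'   sampling rate and epoch window.
#' @param subject_id,group identifiers stored in the recording metadata.
#' @return A list of class `subject_sim`: `recording` (a
#'   [vep_recording()]) and `ground_truth` (designed targets, calibrated
#'   amplitudes `induced_amplitude_uV` / `evoked_scale`, per-trial induced
#'   latencies, artifact epoch indices, truncation diagnostics).
#' @export
simulate_subject <- function(spec, config = NULL, subject_id = "sim",
                             group = NA_character_) {
  stopifnot(inherits(spec, "subject_spec"))
  if (is.null(config))
    config <- pipeline_config(sampling_rate_hz = spec$sampling_rate_hz,
                              epoch_window_ms = c(0, spec$epoch_duration_ms),
                              seed = spec$seed)
  fs <- spec$sampling_rate_hz
  n_ep <- spec$n_epochs
  events_ms <- (seq_len(n_ep) - 1) * spec$isi_ms
  onset_idx <- round(events_ms * fs / 1000)               # 0-based
  n_total <- round((events_ms[n_ep] + spec$isi_ms) * fs / 1000)
  ep_samp <- round(spec$epoch_duration_ms * fs / 1000)

  with_seed(spec$seed, {
    # --- unit component recordings -------------------------------------
    evoked_unit <- numeric(n_total)
    if (!is.null(spec$evoked)) {
      tmpl_t <- (0:(ep_samp - 1)) / fs * 1000
      tmpl <- make_evoked_biphasic(spec$evoked, tmpl_t)
      for (i in seq_len(n_ep))
        evoked_unit[(onset_idx[i] + 1):(onset_idx[i] + ep_samp)] <-
          evoked_unit[(onset_idx[i] + 1):(onset_idx[i] + ep_samp)] + tmpl
    }

    induced_unit <- numeric(n_total)
    latencies <- rep(NA_real_, n_ep)
    n_truncated <- 0L
    if (!is.null(spec$induced)) {
      ind <- spec$induced
      latencies <- stats::rnorm(n_ep, ind$peak_latency_ms,
                                ind$latency_jitter_sd_ms)
      w <- ind$width_ms
      # mass falling outside the analysis epoch window (diagnostic only)
      outside <- stats::pnorm(0, latencies, w) +
        stats::pnorm(spec$epoch_duration_ms, latencies, w,
                     lower.tail = FALSE)
      n_truncated <- sum(outside > 0.01)
      half <- ceiling(6 * w * fs / 1000)
      for (i in seq_len(n_ep)) {
        ctr <- onset_idx[i] + latencies[i] * fs / 1000    # 0-based, fractional
        lo <- max(0L, floor(ctr - half)); hi <- min(n_total - 1L,
                                                    ceiling(ctr + half))
        if (lo > hi) next
        idx <- lo:hi
        induced_unit[idx + 1L] <- induced_unit[idx + 1L] +
          exp(-0.5 * ((idx - ctr) / (w * fs / 1000))^2)
      }
    }

    # --- artifact epoch selection --------------------------------------
    n_art <- round(spec$artifact_fraction * n_ep)
    art_idx <- if (n_art > 0) sort(sample.int(n_ep, n_art)) else integer(0)
    scale_artifacts <- function(x) {
      for (i in art_idx) {
        rng <- (onset_idx[i] + 1):(onset_idx[i] + ep_samp)
        x[rng] <- x[rng] * spec$artifact_gain
      }
      x
    }

    # --- amplitude calibration -----------------------------------------
    # Noise-free self-calibration against the full measurement chain:
    # artifact-scaled unit component recordings are pushed through
    # DC-subtract + band-pass + epoching, the 2-SD kept set is found by
    # fixed point (rejection depends on the amplitudes being solved), and
    # the induced amplitude / evoked scale are solved so the designed
    # observables hold exactly on the noise-free kept set.
    a_i <- if (!is.null(spec$induced)) spec$induced$amplitude_uV else 0
    a_e <- 1
    need_st <- !is.na(spec$target_st_vep_uV) && !is.null(spec$induced)
    need_pp <- !is.na(spec$n1p1_design_uV) && !is.null(spec$evoked)
    pp_warned <- FALSE
    if (need_st || need_pp) {
      ind_stats <- if (!is.null(spec$induced))
        unit_pipeline_stats(scale_artifacts(induced_unit), fs, events_ms,
                            config$epoch_window_ms, config$filter)
      ev_stats <- if (!is.null(spec$evoked))
        unit_pipeline_stats(scale_artifacts(evoked_unit), fs, events_ms,
                            config$epoch_window_ms, config$filter)
      me <- if (is.null(ev_stats)) numeric(n_ep) else ev_stats$means
      mi <- if (is.null(ind_stats)) numeric(n_ep) else ind_stats$means
      kept <- rep(TRUE, n_ep)
      for (pass in 1:6) {
        if (need_st) {
          E_i <- mean(mi[kept])
          if (abs(E_i) < 1e-12)
            stopf("induced component contributes no epoch mean; cannot calibrate")
          a_i <- (spec$target_st_vep_uV - a_e * mean(me[kept])) / E_i
        }
        if (need_pp) {
          wf_i <- if (is.null(ind_stats)) 0 else
            a_i * colMeans(ind_stats$data[kept, , drop = FALSE])
          wf_e <- colMeans(ev_stats$data[kept, , drop = FALSE])
          p2p_of <- function(a) {
            wf <- structure(list(samples = a * wf_e + wf_i,
                                 time_axis_ms = ev_stats$time_axis_ms),
                            class = "vep_waveform")
            n1 <- find_n1(wf, config$peak_windows$n1)
            p1 <- find_p1(wf, n1, config$peak_windows$p1)
            p1$amplitude_uV - n1$amplitude_uV
          }
          f <- function(a) p2p_of(a) - spec$n1p1_design_uV
          if (f(1e-9) >= 0) {
            # the jitter-smeared induced activity alone already spans more
            # than the designed peak-to-peak (possible for very small
            # epoch counts or artifact-dominated recordings): leave the
            # evoked complex at its specified scale and flag it
            if (!pp_warned)
              warnf("subject %s: designed N1-P1 %.3f uV unattainable (induced activity alone spans %.3f uV in the peak windows); evoked scale left at 1",
                    subject_id, spec$n1p1_design_uV,
                    p2p_of(1e-9))
            pp_warned <- TRUE
            a_e <- 1
            need_pp <- FALSE
          } else {
            hi <- 10
            while (f(hi) < 0 && hi < 1e6) hi <- hi * 4
            a_e <- stats::uniroot(f, c(1e-9, hi), tol = 1e-10)$root
          }
        }
        kept_new <- kept_set(a_e * me + a_i * mi, config$reject$k_sd)
        if (identical(kept_new, kept) && pass > 1) break
        kept <- kept_new
      }
    }

    # --- assemble the recording ----------------------------------------
    samples <- a_e * evoked_unit + a_i * induced_unit
    if (spec$noise_sd_uV > 0)
      samples <- samples + stats::rnorm(n_total, 0, spec$noise_sd_uV)
    samples <- scale_artifacts(samples)

    rec <- vep_recording(samples, fs, events_ms,
                         meta = list(subject_id = subject_id, group = group,
                                     seed = spec$seed))
    gt <- list(subject_id = subject_id, group = group,
               target_st_vep_uV = spec$target_st_vep_uV,
               n1p1_design_uV = spec$n1p1_design_uV,
               induced_amplitude_uV = a_i, evoked_scale = a_e,
               n1p1_calibrated = !is.na(spec$n1p1_design_uV) && !pp_warned,
               induced_latencies_ms = latencies,
               n_truncated_bumps = n_truncated,
               artifact_epochs = art_idx, seed = spec$seed)
    structure(list(recording = rec, ground_truth = gt),
              class = "subject_sim")
  })
}

#' Specify a two-group cohort
#'
#' Two groups of simulated subjects sharing one [subject_spec()] template.
#' Per-subject st-VEP targets are drawn from each group's Normal(mean, sd)
#' and per-subject N1-P1 designs likewise. Defaults reproduce a typical
#' episodic-migraine study: 20 patients (EM) with st-VEP 0.824 +/- 0.661
#' uV vs 20 healthy volunteers (HV) with 0.250 +/- 0.605 uV, while the
#' N1-P1 designs (5.895 +/- 1.509 vs 6.201 +/- 1.757 uV) do not differ
#' meaningfully — the dissociation the single-trial statistic is built to
#' expose.
#'
#' Negative drawn st-VEP targets are kept by default (a below-baseline
#' signed mean is physically meaningful and clipping would bias the group
#' mean upward); set `clip_negative_targets = TRUE` to clip at 0 with a
#' log message.
#'
#' @param groups named list of group parameter lists, each with `label`,
#'   `n_subjects` (>= 2), `st_vep_mean_uV`, `st_vep_sd_uV` (>= 0),
#'   `n1p1_mean_uV` (> 0), `n1p1_sd_uV` (>= 0).
#' @param template a [subject_spec()] shared by all subjects.
#' @param seed cohort-level seed (per-subject seeds are derived from it).
#' @param clip_negative_targets clip negative drawn st-VEP targets at 0.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = list(
                          hv = list(label = "HV", n_subjects = 20,
                                    st_vep_mean_uV = 0.250,
                                    st_vep_sd_uV = 0.605,
                                    n1p1_mean_uV = 5.895,
                                    n1p1_sd_uV = 1.509),
                          em = list(label = "EM", n_subjects = 20,
                                    st_vep_mean_uV = 0.824,
                                    st_vep_sd_uV = 0.661,
                                    n1p1_mean_uV = 6.201,
                                    n1p1_sd_uV = 1.757)),
                        template = subject_spec(), seed = 1L,
                        clip_negative_targets = FALSE) {
  if (length(groups) != 2L) stopf("exactly two groups are required")
  for (g in groups) {
    if (g$n_subjects < 2) stopf("each group needs >= 2 subjects")
    if (g$st_vep_sd_uV < 0 || g$n1p1_sd_uV < 0) stopf("SDs must be >= 0")
    if (g$n1p1_mean_uV <= 0) stopf("'n1p1_mean_uV' must be > 0")
  }
  structure(list(groups = groups, template = template,
                 seed = as.integer(seed),
                 clip_negative_targets = clip_negative_targets),
            class = "cohort_spec")
}

#' Simulate a two-group cohort
#'
#' Draws per-subject design targets for both groups and simulates every
#' subject with [simulate_subject()]. Deterministic from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @param config analysis [pipeline_config()] passed to
#'   [simulate_subject()].
#' @param keep_recordings if `FALSE`, drop each subject's recording after
#'   applying `process` (saves memory on large cohorts).
#' @param process optional function applied to each `subject_sim`
#'   (e.g. the preprocessing + measurement chain); its value is stored in
#'   the subject entry as `$processed`.
#' @param design_n1p1 if `FALSE`, skip the per-subject N1-P1 design (the
#'   evoked complex keeps its template scale in every subject — useful
#'   for replicate-heavy st-VEP calibration studies where small epoch
#'   counts make peak-to-peak designs degenerate).
#' @return A list of class `cohort_sim`; one entry per subject with
#'   `subject_id`, `group`, `recording`, `ground_truth` (and `processed`
#'   if `process` was given).
#' @export
simulate_cohort <- function(spec, config = NULL, keep_recordings = TRUE,
                            process = NULL, design_n1p1 = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  draws <- with_seed(spec$seed, {
    lapply(spec$groups, function(g) {
      t_st <- stats::rnorm(g$n_subjects, g$st_vep_mean_uV, g$st_vep_sd_uV)
      t_pp <- stats::rnorm(g$n_subjects, g$n1p1_mean_uV, g$n1p1_sd_uV)
      if (spec$clip_negative_targets && any(t_st < 0)) {
        message(sprintf("clipping %d negative st-VEP target(s) in group %s",
                        sum(t_st < 0), g$label))
        t_st <- pmax(t_st, 0)
      }
      t_pp <- pmax(t_pp, 0.5)   # N1-P1 designs must stay positive
      list(st = t_st, pp = t_pp)
    })
  })
  out <- list()
  k <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    for (si in seq_len(g$n_subjects)) {
      k <- k + 1L
      sspec <- spec$template
      sspec$target_st_vep_uV <- draws[[gi]]$st[si]
      sspec$n1p1_design_uV <- if (design_n1p1) draws[[gi]]$pp[si] else NA_real_
      sspec$seed <- child_seed(spec$seed, k)
      id <- sprintf("%s%02d", g$label, si)
      sim <- simulate_subject(sspec, config = config, subject_id = id,
                              group = g$label)
      entry <- list(subject_id = id, group = g$label,
                    recording = sim$recording,
                    ground_truth = sim$ground_truth)
      if (!is.null(process)) entry$processed <- process(sim)
      if (!keep_recordings) entry$recording <- NULL
      out[[id]] <- entry
    }
  }
  structure(out, class = "cohort_sim", seed = spec$seed)
}
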