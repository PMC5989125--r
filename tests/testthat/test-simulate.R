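test_that("subject_spec validates its invariants", {
  expect_error(subject_spec(n_epochs = 0), "n_epochs")
  expect_error(subject_spec(epoch_duration_ms = 250.1), "integer sample")
  expect_error(subject_spec(artifact_fraction = 0.6), "artifact_fraction")
  expect_error(subject_spec(artifact_gain = 1), "artifact_gain")
  expect_error(subject_spec(isi_ms = 200), "isi_ms")
})

test_that("simulate_subject: degenerate, protocol-scale and deterministic", {
  # no components, no noise: all-zero recording
  sp0 <- subject_spec(n_epochs = 5, evoked = NULL, induced = NULL,
                      noise_sd_uV = 0, artifact_fraction = 0)
  expect_equal(simulate_subject(sp0)$recording$samples,
               numeric(length(simulate_subject(sp0)$recording$samples)))

  # full protocol: 600 events; epoching yields the 600 x 1250 matrix
  sp <- subject_spec(n_epochs = 600, seed = 2, noise_sd_uV = 0,
                     artifact_fraction = 0)
  sim <- simulate_subject(sp)
  expect_length(sim$recording$event_times_ms, 600L)
  ep <- extract_epochs(sim$recording, c(0, 250))
  expect_equal(dim(ep$data), c(600L, 1250L))
  expect_equal(600L * 1250L, 750000L)

  # bit-identical under the same seed
  spn <- tiny_subject(n_epochs = 20, seed = 77)
  s1 <- simulate_subject(spn); s2 <- simulate_subject(spn)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_subject(tiny_subject(n_epochs = 20, seed = 78))
  expect_false(identical(s1$recording$samples, s3$recording$samples))
})

test_that("simulate_subject ground truth records design and nuisance state", {
  sp <- tiny_subject(n_epochs = 50, seed = 5, target_st_vep_uV = 0.6,
                     n1p1_design_uV = 6, artifact_fraction = 0.1)
  gt <- suppressWarnings(simulate_subject(sp))$ground_truth
  expect_equal(gt$target_st_vep_uV, 0.6)
  expect_equal(gt$n1p1_design_uV, 6)
  expect_length(gt$induced_latencies_ms, 50L)
  expect_equal(length(gt$artifact_epochs), 5L)
  expect_true(is.finite(gt$induced_amplitude_uV) &&
                is.finite(gt$evoked_scale))
  expect_type(gt$n1p1_calibrated, "logical")

  # at a benign artifact rate the design is attainable and amplitudes
  # keep their physical signs
  gt2 <- simulate_subject(tiny_subject(n_epochs = 60, seed = 6,
                                       target_st_vep_uV = 0.6,
                                       n1p1_design_uV = 6))$ground_truth
  expect_true(gt2$n1p1_calibrated)
  expect_gt(gt2$induced_amplitude_uV, 0)
  expect_gt(gt2$evoked_scale, 0)
})

test_that("noise-free self-calibration realizes the designed observables", {
  for (target in c(-0.2, 0.25, 0.824)) {
    sp <- tiny_subject(n_epochs = 40, seed = 13, noise_sd_uV = 0,
                       artifact_fraction = 0, target_st_vep_uV = target)
    m <- measure_subject(simulate_subject(sp))
    expect_equal(m$st$st_vep_uV, target, tolerance = 1e-6)
  }
})

test_that("simulate_cohort draws per-group designs reproducibly", {
  # sd 0: every subject in a group shares the designed target
  cs <- cohort_spec(groups = list(
    a = list(label = "A", n_subjects = 2, st_vep_mean_uV = 0.8,
             st_vep_sd_uV = 0, n1p1_mean_uV = 6, n1p1_sd_uV = 0),
    b = list(label = "B", n_subjects = 2, st_vep_mean_uV = 0.2,
             st_vep_sd_uV = 0, n1p1_mean_uV = 6, n1p1_sd_uV = 0)),
    template = tiny_subject(n_epochs = 8), seed = 3)
  sims <- simulate_cohort(cs)
  expect_length(sims, 4L)
  tg <- vapply(sims, function(s) s$ground_truth$target_st_vep_uV, 1)
  expect_equal(unname(tg), c(0.8, 0.8, 0.2, 0.2))
  expect_equal(vapply(sims, `[[`, "", "group"),
               c(A01 = "A", A02 = "A", B01 = "B", B02 = "B"))

  # deterministic from the cohort seed
  sims2 <- simulate_cohort(cs)
  expect_identical(sims$A01$recording$samples, sims2$A01$recording$samples)

  # law-of-large-numbers check on the target sampler at protocol scale
  cs2 <- cohort_spec(template = tiny_subject(n_epochs = 4), seed = 8)
  cs2$groups$hv$n_subjects <- 20; cs2$groups$em$n_subjects <- 20
  sims3 <- suppressWarnings(simulate_cohort(cs2))
  for (g in c("HV", "EM")) {
    pars <- if (g == "HV") c(0.250, 0.605) else c(0.824, 0.661)
    tg <- vapply(sims3[vapply(sims3, `[[`, "", "group") == g],
                 function(s) s$ground_truth$target_st_vep_uV, 1)
    expect_lt(abs(mean(tg) - pars[1]), 3 * pars[2] / sqrt(20))
  }

  # negative-target clipping is opt-in and logged
  cs3 <- cohort_spec(template = tiny_subject(n_epochs = 4), seed = 11,
                     clip_negative_targets = TRUE)
  cs3$groups$hv$n_subjects <- 10; cs3$groups$em$n_subjects <- 2
  expect_message(sims4 <- suppressWarnings(simulate_cohort(cs3)), "clipping")
  tg <- vapply(sims4, function(s) s$ground_truth$target_st_vep_uV, 1)
  expect_true(all(tg >= 0))
})

test_that("fig1 demo: structure, progressive averaging and band contrast", {
  d <- simulate_fig1_demo(seed = 2)
  expect_equal(dim(d$trials), c(7L, length(d$time_axis_ms)))
  expect_equal(d$progressive[1, ], d$trials[1, ])
  # progressive row n is the running mean of trials 1..n (oracle: colMeans)
  expect_equal(d$progressive[5, ], colMeans(d$trials[1:5, ]))

  # n_trials = 1: the average is the single trial
  d1 <- simulate_fig1_demo(n_trials = 1, seed = 4)
  expect_equal(d1$progressive[1, ], d1$trials[1, ])

  expect_error(simulate_fig1_demo(epoch_span_ms = c(0, 500)), "0-600")

  # after 7 trials the synchronized band dominates the unsynchronized one
  ratios <- vapply(1:10, function(s) {
    d <- simulate_fig1_demo(seed = s)
    avg <- d$progressive[7, ]
    band_rms(avg, d$time_axis_ms, d$sync_band_ms) /
      band_rms(avg, d$time_axis_ms, d$unsync_band_ms)
  }, 1)
  expect_true(all(ratios > 5))

  # the synchronized component survives averaging: mean band RMS across
  # seeds within 10% of the component's own RMS (residual unsynchronized
  # power interferes at n = 7, hence the Monte-Carlo average)
  pres <- vapply(1:10, function(s) {
    d <- simulate_fig1_demo(seed = 100 + s)
    band_rms(d$progressive[7, ], d$time_axis_ms, d$sync_band_ms) /
      band_rms(d$sync_component, d$time_axis_ms, d$sync_band_ms)
  }, 1)
  expect_lt(abs(mean(pres) - 1), 0.1)

  # unsynchronized activity attenuates toward the 1/sqrt(n) law
  att <- vapply(1:10, function(s) {
    d <- simulate_fig1_demo(seed = 200 + s)
    u_avg <- colMeans(d$unsync_components)
    band_rms(u_avg, d$time_axis_ms, c(0, 600)) /
      mean(vapply(1:7, function(i)
        band_rms(d$unsync_components[i, ], d$time_axis_ms, c(0, 600)), 1))
  }, 1)
  expect_lt(abs(mean(att) - 1 / sqrt(7)), 0.15)
})
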