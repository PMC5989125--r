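test_that("evoked biphasic complex: degenerate cases and closed form", {
  t_ms <- (0:1249) / 5  # 250 ms at 5 kHz
  zero <- component_spec("evoked_biphasic", amplitude_uV = 0,
                         n1_amplitude_uV = 0)
  expect_equal(make_evoked_biphasic(zero, t_ms), numeric(1250))

  # equal-area lobes cancel in the signed mean
  A <- 3
  sp <- component_spec("evoked_biphasic", peak_latency_ms = 100,
                       amplitude_uV = A, width_ms = 8,
                       n1_latency_ms = 75, n1_amplitude_uV = -A)
  v <- make_evoked_biphasic(sp, t_ms)
  expect_lt(abs(mean(v)), 1e-6 * A)

  # closed-form oracle: evaluate the two-Gaussian sum on the grid directly
  oracle <- -A * exp(-0.5 * ((t_ms - 75) / 8)^2) +
    A * exp(-0.5 * ((t_ms - 100) / 8)^2)
  expect_equal(v, oracle)
  expect_rel(max(v), A, 0.01)
  # peak sits at the P1 latency up to the pull of the overlapping N1 lobe
  expect_equal(t_ms[which.max(v)], t_ms[which.max(oracle)])
  expect_lt(abs(t_ms[which.max(v)] - 100), 1)

  bad <- component_spec("evoked_biphasic", peak_latency_ms = 400)
  expect_error(make_evoked_biphasic(bad, t_ms), "400")
})

test_that("induced monophasic bump: jitter semantics and mean contribution", {
  t_ms <- (0:1249) / 5
  sp <- component_spec("induced_monophasic", peak_latency_ms = 100,
                       amplitude_uV = 4.109, width_ms = 20,
                       latency_jitter_sd_ms = 0)
  v <- make_induced_monophasic(sp, t_ms)
  expect_equal(attr(v, "latency_ms"), 100)

  # jitter 0 is identical to the fixed-latency bump
  spj <- sp; spj$latency_jitter_sd_ms <- 25
  vf <- make_induced_monophasic(spj, t_ms, latency_ms = 100)
  expect_equal(as.numeric(v), as.numeric(vf))

  # epoch signed mean matches the numeric-integration oracle (0.824 uV
  # for A = 4.109, sigma 20, T 250)
  oracle <- stats::integrate(function(t)
    4.109 * exp(-0.5 * ((t - 100) / 20)^2), 0, 250)$value / 250
  expect_rel(mean(v), oracle, 1e-3)
  expect_rel(mean(v), 0.824, 5e-3)

  # mean contribution is latency-invariant (up to edge truncation)
  v2 <- make_induced_monophasic(sp, t_ms, latency_ms = 140)
  expect_rel(mean(v2), mean(v), 0.01)

  expect_warning(make_induced_monophasic(sp, t_ms, latency_ms = 10),
                 "outside")
})

test_that("600-trial average of a jittered bump attenuates per the Gaussian-convolution law", {
  t_ms <- (0:1249) / 5
  sigma <- 20
  sp <- component_spec("induced_monophasic", peak_latency_ms = 125,
                       amplitude_uV = 1, width_ms = sigma,
                       latency_jitter_sd_ms = 3 * sigma)
  set.seed(7)
  lat <- rnorm(600, 125, 3 * sigma)
  avg <- rowMeans(vapply(lat, function(L)
    as.numeric(suppressWarnings(
      make_induced_monophasic(sp, t_ms, latency_ms = L))),
    numeric(length(t_ms))))
  # closed form: peak attenuates by sigma / sqrt(sigma^2 + jitter^2)
  expect_lt(max(avg), 0.4)
  expect_rel(max(avg), sigma / sqrt(sigma^2 + (3 * sigma)^2), 0.10)
})

test_that("calibrate_induced_amplitude inverts the mean-contribution formula", {
  expect_equal(calibrate_induced_amplitude(0, 20, 250), 0)
  expect_error(calibrate_induced_amplitude(1, -1, 250), "width")
  expect_error(calibrate_induced_amplitude(1, 20, 0), "duration")

  # brute-force oracle: search the amplitude whose simulated noise-free
  # epoch mean hits 0.824
  t_ms <- (0:1249) / 5
  mean_of <- function(A) {
    sp <- component_spec("induced_monophasic", peak_latency_ms = 100,
                         amplitude_uV = A, width_ms = 20)
    mean(make_induced_monophasic(sp, t_ms, latency_ms = 100))
  }
  brute <- uniroot(function(A) mean_of(A) - 0.824, c(0.1, 50),
                   tol = 1e-9)$root
  expect_lt(abs(calibrate_induced_amplitude(0.824, 20, 250) - brute), 1e-2)
  expect_rel(calibrate_induced_amplitude(0.824, 20, 250), 4.109, 1e-3)

  # round trip: calibrate then simulate a noise-free epoch
  for (target in c(0.25, 0.824, 2)) {
    A <- calibrate_induced_amplitude(target, 20, 250)
    expect_rel(mean_of(A), target, 0.005)
  }
})

test_that("oscillatory component respects envelope and phase contract", {
  t_ms <- seq(-100, 700, by = 1)
  sp <- component_spec("oscillatory", amplitude_uV = 2, freq_hz = 10,
                       phase = "fixed", support_ms = c(200, 400))
  v <- make_oscillatory(sp, t_ms)
  expect_true(all(v[t_ms < 200 | t_ms > 400] == 0))
  expect_gt(max(abs(v)), 1.5)
  set.seed(1)
  spr <- component_spec("oscillatory", phase = "random")
  p1 <- attr(make_oscillatory(spr, t_ms), "phase_rad")
  p2 <- attr(make_oscillatory(spr, t_ms), "phase_rad")
  expect_false(isTRUE(all.equal(p1, p2)))
})
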