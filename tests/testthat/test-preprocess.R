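test_that("dc_subtract removes exactly the whole-recording mean", {
  rec <- vep_recording(rep(5, 1000), 1000)
  expect_equal(dc_subtract(rec)$samples, numeric(1000))

  x <- sin(2 * pi * (1:1000) / 50)  # integer cycles: already zero-mean
  x <- x - mean(x)
  expect_equal(dc_subtract(vep_recording(x, 1000))$samples, x)

  ramp <- seq(0, 10, length.out = 101)
  out <- dc_subtract(vep_recording(ramp, 1000))$samples
  expect_equal(out, ramp - 5)
  expect_lt(abs(mean(out)), 1e-9)
})

test_that("bandpass matches the analytic Butterworth frequency response", {
  fs <- 5000
  t <- (0:(4 * fs - 1)) / fs  # 4 s
  mid <- seq(fs, 3 * fs)      # avoid edges when measuring amplitude
  amp_after <- function(f_hz) {
    rec <- vep_recording(sin(2 * pi * f_hz * t), fs)
    max(abs(bandpass(rec)$samples[mid]))
  }
  # oracle: squared-magnitude order-4 Butterworth band-pass gain
  gain <- function(f) 1 / (1 + ((f^2 - 1 * 100) / (f * 99))^8)
  expect_rel(amp_after(10), gain(10), 0.05)
  expect_rel(amp_after(10), 1, 0.05)
  expect_lt(amp_after(0.25), 0.1)
  expect_lt(amp_after(500), 0.1)
  expect_lt(abs(amp_after(500) - gain(500)) , 0.02)

  expect_error(bandpass(vep_recording(t, fs), high_hz = 2500), "Nyquist")
  expect_error(bandpass(vep_recording(t, fs), low_hz = 0), "low_hz")
})

test_that("bandpass is zero-phase: a 10 Hz sinusoid is not shifted", {
  fs <- 5000
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- bandpass(vep_recording(x, fs))$samples
  mid <- seq(fs, 3 * fs)
  lags <- -25:25
  cc <- vapply(lags, function(L)
    sum(x[mid] * y[mid + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("extract_epochs cuts half-open stimulus-locked windows", {
  fs <- 5000
  events <- (0:9) * 300
  n <- round((max(events) + 300) * fs / 1000)
  rec <- vep_recording(seq_len(n), fs, events)
  ep <- extract_epochs(rec, c(0, 250))
  expect_equal(dim(ep$data), c(10L, 1250L))
  expect_equal(ep$time_axis_ms[1], 0)
  expect_equal(ep$time_axis_ms[2] - ep$time_axis_ms[1], 0.2)
  # epoch i starts exactly at its onset sample
  expect_equal(ep$data[2, 1], round(300 * fs / 1000) + 1)

  # 0 events: empty epoch set, no error
  ep0 <- extract_epochs(vep_recording(1:100, fs), c(0, 10))
  expect_equal(nrow(ep0$data), 0L)

  # constant recording: every epoch constant
  epc <- extract_epochs(vep_recording(rep(2, n), fs, events), c(0, 250))
  expect_true(all(epc$data == 2))

  # event too close to the end is dropped with a warning
  rec2 <- vep_recording(seq_len(1000), fs, c(0, 150))
  expect_warning(ep2 <- extract_epochs(rec2, c(0, 100)), "outside")
  expect_equal(nrow(ep2$data), 1L)
})

test_that("reject_artifacts implements the single-pass 2-SD epoch-mean rule", {
  # identical epochs: SD = 0 branch, nothing rejected
  ep <- make_epochs(matrix(1, 10, 50))
  out <- reject_artifacts(ep)
  expect_equal(out$report$n_rejected, 0L)

  # one gross outlier among zero-mean epochs is exactly what gets cut
  set.seed(1)
  m <- matrix(rnorm(100 * 50, 0, 1), 100)
  m <- m - rowMeans(m)          # force per-epoch means to 0
  m[37, ] <- m[37, ] + 100
  out <- reject_artifacts(make_epochs(m))
  expect_equal(out$report$rejected_indices, 37L)
  expect_false(out$epochs$kept_mask[37])
  expect_equal(sum(out$epochs$kept_mask), 99L)

  # report carries the pre-rejection statistic for every epoch
  expect_equal(out$report$per_epoch_statistic, rowMeans(m))

  # Gaussian epochs: ~2*pnorm(-2) = 4.55% rejected, below the 7% bound
  set.seed(42)
  fr <- replicate(30, {
    g <- make_epochs(matrix(rnorm(600 * 10), 600))
    reject_artifacts(g)$report$n_rejected / 600
  })
  expect_lt(mean(fr), 0.07)
  expect_gt(mean(fr), 0.035)
  expect_lt(mean(fr), 0.055)

  # single-pass contract: second call is a logged no-op
  once <- reject_artifacts(make_epochs(m))
  expect_message(twice <- reject_artifacts(once$epochs), "no-op")
  expect_identical(twice$epochs$kept_mask, once$epochs$kept_mask)

  expect_error(reject_artifacts(make_epochs(matrix(1, 2, 5))), "3 epochs")
})

test_that("preprocess applies the fixed chain: DC, filter, epoch, reject", {
  sim <- simulate_subject(tiny_subject(n_epochs = 30, seed = 9))
  cfg <- pipeline_config()
  ep <- preprocess(sim$recording, cfg)
  manual <- reject_artifacts(
    extract_epochs(
      bandpass(dc_subtract(sim$recording), cfg$filter$low_hz,
               cfg$filter$high_hz, cfg$filter$order),
      cfg$epoch_window_ms),
    cfg$reject$k_sd)$epochs
  expect_equal(ep$data, manual$data)
  expect_identical(ep$kept_mask, manual$kept_mask)
  # filtering happens on the continuous signal before epoching by
  # construction; the chain above is the only path to epochs
  expect_s3_class(ep$meta$rejection_report, "rejection_report")
})
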