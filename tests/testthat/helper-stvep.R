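# Small builders shared across test files. All fixtures are generated in
# code; no data files.

make_epochs <- function(data, fs = 5000, t0 = 0) {
  data <- as.matrix(data)
  vep_epochs(data, t0 + (0:(ncol(data) - 1)) / fs * 1000,
             sampling_rate_hz = fs)
}

# A fast small subject spec for pipeline tests (few epochs, default fs).
tiny_subject <- function(n_epochs = 40, seed = 1, ...) {
  subject_spec(n_epochs = n_epochs, seed = seed, ...)
}

# Reduced-rate subject used for replicate-heavy calibration loops:
# PSD-matched noise so epoch-mean noise is comparable to the 5 kHz default.
fast_subject <- function(n_epochs = 24, seed = 1, ...) {
  subject_spec(n_epochs = n_epochs, sampling_rate_hz = 1000,
               noise_sd_uV = 20 * sqrt(1000 / 5000), seed = seed, ...)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
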