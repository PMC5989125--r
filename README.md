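# stvep — single-trial visual evoked potential analysis

`stvep` is an R package for analyzing pattern-reversal visual evoked
potentials (VEPs) recorded from a single occipital channel (Oz–Fz), with a
focus on the **single-trial VEP amplitude (st-VEP)**: the signed mean
voltage of each post-stimulus epoch, grand-averaged over un-artifacted
trials. Unlike the conventional averaged-waveform readout, this statistic is
insensitive to trial-to-trial latency jitter, so it captures
stimulus-*induced* (unsynchronized) activity that point-by-point averaging
destroys.

It is aimed at clinical neurophysiologists and methods researchers who want
a tested, reproducible implementation of the statistic, its preprocessing
chain, and a calibrated synthetic-data generator for power and validity
studies.

## The statistic

For subject *s* with epochs *x*\_*i*(*t*), *t* ∈ [0, 250) ms:

- per-epoch mean amplitude: ē\_*i* = (1/T) Σ\_*t* *x*\_*i*(*t*)
- st-VEP amplitude: (Σ\_{i kept} ē\_*i*) / *n*\_kept, where "kept" epochs are
  those surviving the 2-SD rule |ē\_*i* − mean(ē)| ≤ 2·SD(ē)
- conventional comparator: N1 = most negative point of the averaged
  waveform in 60–90 ms, P1 = most positive point following N1 in 80–120 ms,
  N1–P1 = P1 − N1 peak-to-peak amplitude (µV)

Preprocessing (fixed order): whole-recording DC subtraction → zero-phase
1–100 Hz band-pass of the continuous signal → epoching into 250 ms
stimulus-locked sweeps → 2-SD epoch-mean artifact rejection.

Group inference is a pooled two-sample Student *t*-test (df = n₁+n₂−2),
preceded by a Shapiro–Wilk normality screen, runnable on raw per-subject
values or directly on printed group summaries ("worked-example mode").

## Worked example

Recompute the headline group comparison from published summary statistics
(st-VEP 0.824 ± 0.661 µV in 20 migraine patients vs 0.250 ± 0.605 µV in 20
controls; conventional N1–P1 5.895 ± 1.509 vs 6.201 ± 1.757 µV):

```r
library(stvep)

ttest_summary(group_summary("EM", 20, 0.824, 0.661),
              group_summary("HV", 20, 0.250, 0.605))
#> <test_result> pooled two-sample Student t: t(38) = 2.8647, p = 0.006763, diff = 0.5740

ttest_summary(group_summary("HV", 20, 5.895, 1.509),
              group_summary("EM", 20, 6.201, 1.757))
#> <test_result> pooled two-sample Student t: t(38) = -0.5909, p = 0.5581, diff = -0.3060
```

The single-trial statistic separates the groups (p = 0.007) while the
conventional peak-to-peak amplitude does not (p = 0.56) — the dissociation
the package is built around.

End-to-end on synthetic data: simulate the full 20+20-subject, 600-epoch
protocol and run the pipeline on both metrics (~1 minute on one CPU; a
single cohort draw, so p-values vary seed to seed around the designed
power of ~0.80):

```r
res <- run_pipeline(cohort_spec(seed = 1))
res$st_vep_test$test
#> <test_result> pooled two-sample Student t: t(38) = -3.2265, p = 0.00258, diff = -0.5543
res$n1p1_test$test
#> <test_result> pooled two-sample Student t: t(38) = -0.7965, p = 0.4307, diff = -0.4004
head(res$table[, c("subject_id", "group", "st_vep_uV", "n1p1_uV", "rejected_fraction")], 3)
#>   subject_id group  st_vep_uV  n1p1_uV rejected_fraction
#> 1       HV01    HV -0.1315291 8.031984        0.02833333
#> 2       HV02    HV  0.3772508 7.642255        0.03666667
#> 3       HV03    HV -0.2556639 6.563465        0.02833333
```

(The difference is HV minus EM, hence negative.) Per-subject st-VEPs
scatter around their group means (negative values are legitimate: a signed
mean can fall below baseline), rejection fractions stay below 7%, and the
st-VEP comparison is significant while N1–P1 is not. Subjects whose drawn
N1–P1 design falls below what the jitter-smeared induced activity alone
spans are flagged with a warning and keep the template evoked complex.

The seven-trial averaging demonstration (synchronized activity survives
averaging, random-phase activity cancels as 1/√n):

```r
d <- simulate_fig1_demo(seed = 1)
avg <- d$progressive[7, ]
band_rms(avg, d$time_axis_ms, d$sync_band_ms)    # 1.357 uV: preserved
band_rms(avg, d$time_axis_ms, d$unsync_band_ms)  # 0.096 uV: destroyed
```

## Command line

```sh
inst/cli/stvep simulate   --cohort cohort.json --out rec/ --seed 1
inst/cli/stvep preprocess --in rec/ --out epochs/ --low 1 --high 100 --reject-sd 2
inst/cli/stvep stvep      --in epochs/ --out results/
inst/cli/stvep cvep       --in epochs/ --out results/
inst/cli/stvep stats      --summary-mode --a "0.824,0.661,20" --b "0.250,0.605,20"
inst/cli/stvep run        --out results/ --seed 1
inst/cli/stvep fig1-demo  --out demo/ --seed 1
```

Recordings and epoch sets are text files (one-column samples / TSV epoch
matrices) with JSON sidecars carrying sampling rate, event times, kept
masks, units and provenance.

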