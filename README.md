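# ushrv — validity of ultra-short time-domain HRV

Routine 10 s clinical ECGs are a vast, mostly untapped source of heart
rate variability (HRV) phenotypes, but resting time-domain HRV is
conventionally measured on recordings of several minutes. `ushrv` is
an R package for the question every large cohort study faces before
reusing short ECGs: **how much of the "actual" HRV of a 240–300 s
gold-standard recording is captured by SDNN and RMSSD computed from
10 s, 30 s and 120 s segments of it — and how much of the apparent
agreement is a trivial consequence of the segment being part of the
recording?**

For a window of NN intervals $x_1,\dots,x_N$ (ms):

- $\mathrm{SDNN} = \sqrt{\tfrac{1}{N-1}\sum_i (x_i-\bar x)^2}$ —
  overall variability, all frequency components;
- $\mathrm{RMSSD} = \sqrt{\tfrac{1}{N-1}\sum_i (x_{i+1}-x_i)^2}$ —
  fast (parasympathetic) variability only.

Agreement of each short-segment measure with the gold standard is
quantified on the natural-log scale by Pearson r (Fisher-z CI),
Bland–Altman bias and 95% limits of agreement
($\mathrm{bias} \pm 1.96\,\mathrm{SD}$ of the paired differences),
Cohen's d (bias over the between-subject SD of the gold-standard
measure), and ICC(A,1) among the repeated 10 s windows. The part-whole
inflation of all of these is measured by a bootstrap null simulation:
each subject's *remainder* HRV is approximated by the
interval-count-weighted variance decomposition

$$
HRV_{rem}^2=\frac{HRV_{tot}^2 (N_{tot}{-}1)-HRV_{short}^2 (N_{short}{-}1)}{N_{tot}-N_{short}-1},
$$

short and remainder values are resampled independently across
subjects, recombined into simulated totals by the inverse formula, and
the 2.5th–97.5th percentiles of each statistic over 1,000 repetitions
form its null 95% reference range.

Because cohort-scale beat-to-beat recordings are rarely shareable, the
package includes a seeded synthetic NN-interval generator (respiratory
and low-frequency sinusoids at beat-time sampling, random-walk drift,
white noise, log-normal across-subject amplitudes) calibrated to a
resting adult population: median SDNN ≈ 32 ms, median RMSSD ≈ 24.5 ms,
mean heart rate ≈ 68 bpm, and SDNN (but not RMSSD) growing with
recording length.

## Worked example

```r
library(ushrv)
pop <- generate_population(population_spec(n_subjects = 100, seed = 7))
ana <- analyze_population(pop, segment_seed = 1, boot_seed = 2, n_boot = 500)
print(ana)
#> <hrv_analysis> 100 subjects analysed, 0 excluded
#>    label   n sdnn_mean rmssd_mean
#> 1  10s_1 100     26.39      25.95
#> 2  10s_2 100     26.88      26.09
#> 3  10s_3 100     26.85      26.52
#> 4 Avg10s 100     26.70      26.18
#> 5    30s 100     27.38      26.75
#> 6   120s 100     29.44      26.64
#> 7  total 100     34.30      26.66
```

Mean SDNN climbs ~8 ms from the 10 s windows to the total recording
(slow variability accumulates with window length) while mean RMSSD
moves by well under 1 ms. The agreement table shows the consequence:

```r
print(ana$agreement)
#> <hrv_agreement>
#>     metric  label   n     r    bias loa_low loa_high cohens_d
#> 1   lnSDNN  10s_1 100 0.604 0.29298 -0.3577   0.9437  0.92546
#> 5   lnSDNN    30s 100 0.722 0.23433 -0.2492   0.7178  0.74018
#> 6   lnSDNN   120s 100 0.839 0.15503 -0.1999   0.5100  0.48971
#> 7  lnRMSSD  10s_1 100 0.944 0.04237 -0.2430   0.3277  0.10409
#> 10 lnRMSSD Avg10s 100 0.982 0.02470 -0.1331   0.1825  0.06068
#> 12 lnRMSSD   120s 100 0.995 0.00277 -0.0768   0.0823  0.00681
#> # (rows abridged)
```

RMSSD from a single 10 s window already correlates at r ≈ 0.94 with
the gold standard with a near-zero bias (d ≈ 0.10); SDNN from the same
window is biased upward by ~0.29 log-units (d ≈ 0.93) and only reaches
r ≈ 0.84 at 120 s. Averaging three 10 s windows (`Avg10s`) narrows the
limits of agreement without touching the bias. The null simulation
then asks whether such correlations could arise from part-whole
overlap alone:

```r
ns <- nullsim_table(ana$subject_hrv, n_reps = 1000, seed = 3,
                    agreement = ana$agreement)
subset(ns, metric == "lnRMSSD" & statistic == "r",
       select = c(label, observed, null_lo, null_hi, verdict))
#>     label  observed     null_lo   null_hi verdict
#> 31  10s_1 0.9441688 -0.12525630 0.2377775   above
#> 46 Avg10s 0.9816642 -0.14095037 0.2552525   above
#> 51    30s 0.9814791 -0.02378392 0.3467671   above
#> 56   120s 0.9951569  0.42208662 0.7304746   above
#> # (rows abridged)
```

Even at 120 s, where sharing ~40% of the intervals would by itself
produce r ≈ 0.42–0.73, the observed correlation sits far above the
null range: short-segment RMSSD reflects genuine within-subject
stability, not bookkeeping.

File-based runs (`run_simulate()`, `run_analyze()`, `run_nullsim()`)
write the same tables as TSV plus seed-carrying manifests; a thin CLI
with verbs `simulate` / `analyze` / `nullsim` / `report` is installed
at `inst/scripts/hrv_pipeline.R`.

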