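---
title: "How ushrv assesses the validity of ultra-short HRV recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ushrv assesses the validity of ultra-short HRV recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Routine clinical ECGs last about 10 seconds, while the standard
recommendation for resting time-domain heart rate variability (HRV) is
a recording of several minutes. `ushrv` implements a complete pipeline
for asking how much of the "actual" HRV — as measured on a 240–300 s
gold-standard recording — is captured by SDNN and RMSSD computed from
(ultra-)short segments of 10 s, 30 s and 120 s cut from that same
recording, and for deciding how much of the apparent agreement is a
trivial consequence of the part-whole design rather than genuine
within-subject stability.

The pipeline has five stages:

1. **Synthetic cohort generation** (`generate_population()`), standing
   in for a resting-cohort dataset of beat-to-beat NN intervals.
2. **Data-quality rules** (`interpolate_artifacts()`,
   `apply_segment_artifact_rules()`).
3. **Window selection and metrics** (`select_segments()`,
   `extract_segment()`, `sdnn()`, `rmssd()`, `avg10s()`).
4. **Agreement statistics** on the natural-log scale
   (`agreement_table()`): Pearson r with Fisher-z CI, Bland–Altman bias
   and 95% limits of agreement (LoA), Cohen's d, and pairwise
   ICC(A,1) among the 10 s windows.
5. **A bootstrap null simulation** (`bootstrap_null()`,
   `nullsim_table()`) built on an interval-count-weighted variance
   decomposition, giving 95% reference ranges for every agreement
   statistic under the null hypothesis of no within-subject agreement
   beyond part-whole overlap.

## The synthetic NN-interval model

Real resting NN-interval series mix fast, respiration-driven
variability with slower oscillations and drift. The generator writes
interval $i$, starting at cumulative beat time $t_i$, as

$$
NN_i = \mu
  + A_{lf}\,\sin(2\pi f_{lf}\,t_i + \phi_{lf})
  + A_{hf}\,\sin(2\pi f_{hf}\,t_i + \phi_{hf})
  + d_i + \varepsilon_i ,
$$

with $d_i$ a Gaussian random walk (per-step SD `drift_sd`),
$\varepsilon_i$ white noise (`noise_sd`), per-subject random phases,
and a hard physiologic floor of 200 ms. Oscillations are evaluated at
the cumulative beat time itself (point-process sampling) because that
is how HRV arises in beat-indexed data; sampling on a uniform clock
would decouple the oscillation phase from the beat sequence.

The slow side is deliberately modelled as an LF sinusoid plus a random
walk rather than 1/f noise: it is the simplest mechanism that makes
SDNN grow with recording length while leaving RMSSD — which only sees
successive differences — nearly length-invariant. That length
dependence is precisely the behaviour the analysis must be able to
detect, so the generator must produce it without hard-coding it into
any metric.

Across subjects, the mean interval is Gaussian (882 ± 120 ms,
i.e. a mean heart rate near 68 bpm) and all amplitude-like parameters
are log-normal, producing the right-skewed HRV distributions that
motivate the log transform used in every downstream analysis.
Frequencies are uniform over the respiratory band (0.18–0.40 Hz) and
the baroreflex band (0.05–0.12 Hz); recording length is uniform on
280–300 s, inside the 239–302 s range the segment selector accepts.

### Calibration

The default amplitude scales (`hf_amp` ~ LN(log 16.5, 0.55), `lf_amp`
~ LN(log 22, 0.55), `noise_sd` ~ LN(log 8.3, 0.5), `drift_sd` ~
LN(log 2.45, 0.55), in ms) were chosen once so that a default cohort
reproduces, for the full-length recording, a median SDNN near 32 ms, a
median RMSSD near 24.5 ms and a mean heart rate near 68 bpm — the
descriptives of a middle-aged general adult population at rest — and a
mean SDNN rise of roughly 9–10 ms from the 10 s average to the total
recording versus about 1 ms for RMSSD. The acceptance suite checks the
medians to ±15% at n = 500.

What the generator does **not** emulate: ectopic-beat physiology
(artifacts are flag-level interval perturbations, halving or doubling),
respiratory frequency wander within a recording, circadian or
posture effects, and any dependence of variability amplitude on heart
rate beyond what the shared subject-level draws induce. Passing tests
on this cohort therefore demonstrate that the *pipeline* behaves
correctly on data with the right covariance structure, not that any
particular clinical population would show the same numerical
agreement.

## Data-quality rules

Artifact runs are linearly interpolated between the nearest
non-artifact neighbours. A gap of duration $D$ is replaced by
$\mathrm{round}(D/\bar v)$ intervals on the straight line between the
anchor values $v_a, v_b$ (with $\bar v$ their mean), which preserves
total recording time to within one interval; a recording whose
interpolated fraction exceeds 5% of intervals is discarded. The 5%
rule is counted over intervals, not seconds — an assumption recorded
in the run manifest. The interpolant itself is deliberately simple:
downstream analysis only consumes the interpolated fraction and the
repaired interval values, and the 5% gate, not the interpolation
method, is the analysed behaviour.

Inside an analysis window the rules are stricter, because one
interruption destroys a run of successive differences: a single
artifact interval at the very start or end of the window is trimmed
and the rest used; any interior artifact, or more than one, excludes
the window (and, since every label is required, the subject).
"Start or end" is interpreted at interval granularity — intervals,
not beats, are the unit of both SDNN and RMSSD. Interpolated (as
opposed to artifact) intervals inside windows are retained; they were
already charged against the recording-level 5% budget.

## Windows and metrics

From each recording the pipeline takes the total window, a 30 s and a
120 s window anchored at the start, and three 10 s windows placed by
continuous-uniform rejection sampling until pairwise disjoint (only
the three 10 s windows are mutually constrained; they may overlap the
anchored windows). An interval belongs to the window containing its
*terminating* beat, with a half-open `(start, end]` convention, so a
tiling of the recording partitions the intervals exactly — the
bookkeeping the variance decomposition needs.

SDNN is the sample SD (divisor $N-1$; the divisor the decomposition
formula assumes), RMSSD the root mean square of the $N-1$ successive
differences. `Avg10s` averages the three 10 s measures on the raw
millisecond scale and takes the log of the mean; at the printed
precision of typical cohort tables this is indistinguishable from the
mean of logs, and the choice is recorded in the manifest. Degenerate
zero-valued measures (possible on synthetic constant input) become
`-Inf` on the log scale and are dropped from log-scale analyses with a
count.

## Agreement statistics

All comparisons are on the natural-log scale, short segment versus the
total recording over subjects: Pearson r with a Fisher-z 95% CI;
Bland–Altman bias (gold minus short) with LoA = bias ± 1.96·SD of the
differences (the 1.96 multiplier, not a t quantile, matches the
standard LoA definition and is indistinguishable at cohort sizes);
Cohen's d = bias / SD of the total-recording measure, with a
nonparametric bootstrap CI over subjects (2,000 resamples by default)
since no analytic CI is standard for this ratio; and ICC(A,1) — the
two-way random-effects, absolute-agreement, single-rater intraclass
correlation — among the 10 s windows, computed from the two-way ANOVA
mean squares with the McGraw–Wong F-based CI. Single-rater (not
average-measures) ICC is used because individual 10 s recordings are
what a clinic would reuse. Subjects enter each comparison only with
complete finite pairs; nothing is imputed.

## The bootstrap null simulation

Part-whole overlap alone induces agreement: a 120 s segment covers
roughly 40% of its parent recording, so even if the remainder were
exchanged between subjects the segment would correlate with the
total. To quantify that floor, the remainder HRV of each subject is
approximated on the raw millisecond scale by the variance
decomposition

$$
HRV_{rem}^2 =
\frac{HRV_{tot}^2\,(N_{tot}-1) - HRV_{short}^2\,(N_{short}-1)}
     {N_{tot}-N_{short}-1},
$$

applied identically to SDNN and RMSSD. For RMSSD the identity is only
approximate and the radicand can be negative; such pairs are dropped
and counted, never clamped to zero, because clamping would distort the
lower tail of the null distribution. Each of the (default) 1,000
repetitions draws n short values and, independently, n remainder
values with replacement — each value carrying its own interval count,
since the formulas are N-weighted and counts are subject-specific —
recombines every pair into a simulated total with the inverse formula,
log-transforms, and computes r, bias, LoA bounds and Cohen's d. The
2.5th/97.5th percentiles (inclusive linear interpolation, R type 7,
stated in the manifest) across repetitions form the 95% reference
range, and each observed statistic is classified below / inside /
above its range.

Decomposition and recombination must run on the raw scale — the
variance algebra is meaningless on logs — with the log transform
applied afterwards for the agreement statistics; the ordering is
forced by the algebra. For `Avg10s` the short value entering the
decomposition is the Avg10s measure with N set to the mean 10 s
interval count; this is an interpretation (recorded in the output
metadata) since no canonical choice exists for an averaged segment.
Repetitions that happen to draw zero-variance vectors are redrawn with
a logged count.

Two algebraic subtleties are worth stating. First, recombination
exactly inverts decomposition (round-trip identity to 10⁻⁹ relative
tolerance; tested over 10,000 randomized inputs). Second, equal
values do *not* pass through exactly: decomposing a recording with
$HRV_{short}=HRV_{tot}=c$ yields
$c\sqrt{(N_{tot}-N_{short})/(N_{tot}-N_{short}-1)}$, a fraction of a
percent above $c$ at realistic counts. The unit tests assert the exact
value rather than pretending the divisors cancel.

### A known, deliberate red flag at 120 s

On the default cohort the observed correlations sit far above their
null ranges for every label and metric — the key validity finding —
and the observed biases fall inside their null ranges for the 10 s,
Avg10s and 30 s labels. At 120 s, however, the observed bias falls
*below* its null range for both metrics. This is not a bug but a
property of the null construction: recombining *independently drawn*
short and remainder values narrows the log-scale spread of simulated
totals relative to observed totals (a Jensen/AM–GM effect of order
$w(1-w)\,\mathrm{Var}(\ln HRV^2)/2$ with $w$ the short segment's
interval-count share), which inflates the mean simulated log-total —
and hence the null bias — by several hundredths of a log-unit when
$w \approx 0.4$. At the short labels $w$ is small and the effect is
negligible. A Monte-Carlo check with realistic cohort marginals shows
the effect is inherent to the stated procedure, not to this
implementation, so the package reports the verdict honestly rather
than adjusting the simulation to hide it.

## Numerical and design choices

* **Seeding.** Every stochastic entry point takes an explicit seed and
  restores the caller's RNG state; population generation derives
  per-subject child seeds from one stream, so outputs are pure
  functions of (inputs, seed). Run manifests persist all seeds.
* **Problem sizes.** The default cohort used by the acceptance
  analysis is n = 500 subjects with 1,000 bootstrap repetitions —
  large enough that the qualitative agreement ordering and the
  calibration medians are stable across seeds (checked at several),
  small enough to run interactively.
* **Degenerate inputs.** Fewer than 2 intervals make SDNN/RMSSD
  undefined (error, or window rejection inside the pipeline); zero
  variance makes r and ICC undefined (error); `sd_total = 0` makes
  Cohen's d undefined (error). Constant and alternating series are
  used as closed-form fixtures throughout the tests.
* **Tie-breaks.** The three 10 s windows are labelled in start-time
  order; artifact perturbations alternate halve/double in draw order;
  rejection sampling redraws all three window starts together.
* **File formats.** A TSV dialect (`subject_id`, `beat_time_s`,
  `nn_ms`, `flag`) carries cohorts; a one-interval-per-line text
  format is provided for interoperability with common NN/RR archives.

## Limitations

The synthetic cohort is a covariance-structure stand-in, not a
physiological simulator; absolute agreement numbers from it should not
be quoted as expectations for any real population. The remainder
decomposition is exact for SDNN only when segment means equal the
grand mean (drift breaks this, by exactly the between-segment mean
term; tested against a brute-force oracle), and approximate for RMSSD.
The null simulation inherits the independence-recombination bias
discussed above at long segment lengths. Frequency-domain HRV is out
of scope entirely.
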