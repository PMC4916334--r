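---
title: "Walking recognition and PAL prediction from accelerometer counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking recognition and PAL prediction from accelerometer counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkcounts)
```

## The problem

Healthy older adults accumulate physical activity through a mixture of
walking and non-walking movement (housekeeping, cycling, gardening, ...).
Understanding how much of daily activity is walking — and whether walking
predicts overall energy expenditure — requires three things from a raw
triaxial accelerometer recording:

1. a movement-intensity currency (**activity counts**),
2. a way to recognize **walking** epochs and group them into bouts, and
3. a regression layer linking daily counts to the **physical activity
   level** (PAL = total energy expenditure / basal metabolic rate, a
   dimensionless index; sedentary adults sit near 1.4, very active ones
   near 2.2).

`walkcounts` implements this pipeline for lower-back triaxial recordings
sampled at a nominal 60 Hz, plus a synthetic-signal generator so the whole
chain can be validated without any real recordings.

## Activity counts

The recording is reduced to 5-second epochs. Within each epoch, each axis
is detrended (mean removal by default), rectified, and integrated by the
rectangular rule; the three per-axis integrals are summed:

$$
\mathrm{counts} \;=\; \sum_{a \in \{x,y,z\}} \frac{1}{f_s}
\sum_{i} \bigl|\,a_i - \bar{a}\,\bigr| \qquad [\mathrm{g\,s}]
$$

Mean removal is the minimal reading of "detrending" and makes the static
gravity component drop out exactly; a linear-trend option exists
(`detrend = "linear"`) for recordings with slow orientation drift.
Summing the three axes is the common composite-counts convention in
actigraphy. Epochs producing fewer than $10^{-3}$ counts/s (strict
less-than) are flagged **inactive** and excluded from all activity time
and count aggregates.

Two numerical notes. First, counts are linear in amplitude and invariant
to constant offsets — both are tested properties. Second, the rectangular
rule's error for a sinusoid of frequency $f$ is
$O\!\left((f/f_s)^2\right)$ but phase-dependent: at 60 Hz it stays below
1% for $f \le 4$ Hz at every phase, while at exactly 5 Hz (12
samples/cycle) the worst-case phase — samples aligned with the
rectification kinks — reaches 2.3%. Body acceleration during walking
lives well below that band edge, so this is irrelevant in practice, but
the test suite asserts the 1% bound only up to 4 Hz and asserts
$O(f_s^{-2})$ convergence at 5 Hz.

## The personalized gait template

Walking is recognized by matching each epoch against a subject-specific
prototype of one gait cycle, built from a laboratory treadmill session
(four speeds, pooled by default). Construction:

1. **Cycle length.** The vector-magnitude signal's autocorrelation is
   scanned for local maxima; the smallest significant peak lag (within
   90% of the best peak) is the candidate period. Because left and right
   steps are rarely identical, gait correlates *more strongly* at the
   stride (two steps) than at the single step, so when the doubled lag
   has a strictly higher autocorrelation the stride is taken as the
   cycle. A symmetric periodic signal never triggers the doubling,
   because sample autocorrelation decays with lag. Signals with no
   autocorrelation peak above 0.3 are rejected as non-periodic
   (calibration-quality error).
2. **Segmentation.** Prominent vector-magnitude peaks at least 0.7 cycle
   lengths apart cut the signal peak-to-peak; segments within ±30% of the
   nominal cycle length become cycles, each mean-removed.
3. **Averaging.** Cycles are linearly resampled to the median cycle
   length, circularly aligned to the first cycle by maximizing
   cross-correlation, averaged pointwise, and mean-removed. Averaging
   cancels cycle-to-cycle noise and leaves the prototype waveform.

The exact prototype construction is a design choice of this package:
any reasonable template-averaging scheme works, because the classifier
is calibrated on the very features the template produces.

## Epoch features and the walking classifier

Each epoch yields two features:

* **SDs** — the population standard deviation of the epoch's vector
  magnitude (signal power), and
* **SDcc** — the population standard deviation of the cross-correlation
  between the mean-removed epoch signal and the template over all
  full-overlap lags (periodicity/shape agreement, a matched filter).

The cross-correlation is deliberately the raw sliding dot product, not a
normalized correlation: amplitude carries intensity information, and any
fixed monotone rescaling is absorbed when the likelihood densities are
calibrated on the same treadmill epochs.

The classifier assumes naive conditional independence of the two
features given walking:

$$
P(\mathrm{walk}) = k \cdot P(\mathrm{SDs}\mid\mathrm{walk})
                     \cdot P(\mathrm{SDcc}\mid\mathrm{walk}),
\qquad
k = \frac{0.5}{0.14 \cdot \max_{\text{calib.\ epochs}}
      P(\mathrm{SDs}\mid\mathrm{walk})P(\mathrm{SDcc}\mid\mathrm{walk})}
$$

The two univariate likelihoods are Gaussian kernel density estimates
with Silverman's bandwidth by default (`density = "kde"`); a log-normal
parametric fit is available. The 0.5 and 0.14 constants are treated as
fixed, configurable parameters.

The resulting score is an *unnormalized* likelihood, not a calibrated
probability: at the best-matching calibration epoch it equals
$0.5/0.14 \approx 3.57$, so it can exceed 1 and its complement can be
negative. The implementation therefore never relies on the complement;
it uses the algebraically equivalent decision rule

$$
\text{walk} \iff \text{joint likelihood} > 0.14 \cdot \text{max joint},
$$

with an exact tie going to non-walk (conservative toward the majority
class; configurable via `tie_rule`). Both forms are tested for
equivalence on a dense feature grid. Inactive epochs bypass the
classifier entirely.

## Bouts, wear time, days and subjects

A walking **bout** is a maximal run of consecutive walk epochs — a
single non-walk epoch ends a bout, with no gap tolerance, which is the
minimal reading of bouts defined by consecutive walking. Bouts shorter
than 60 s are **short walks** (11 five-second epochs or fewer); bouts of
at least 60 s are **long walks**. Daily time in a category is 5 s times
its epoch tally; daily counts are sums over the category's epochs, so
short + long = walking and walking + nonwalking = activity hold exactly
at every level.

A day is **valid** when wear time reaches 10 h (inclusive) and no data
are missing. How wear time is measured is a genuine design choice: here
non-wear is detected as runs of ≥ 60 consecutive minutes of zero-count
epochs (an unworn device registers no body acceleration at all, unlike a
worn-but-idle one, which keeps a noise floor), and wear time is the
recorded duration minus such runs; externally measured wear logs can be
supplied instead. Subject summaries average valid days only — treating
daily activity as an ergodic process, so removing days does not bias the
mean. Category **intensity** for a subject is the ratio of mean daily
counts to mean daily time (counts/min); cohort intensity is the mean of
per-subject intensities, *not* the ratio of cohort means — the only
convention under which a published non-walking row (3.5 kcounts over
500 min ↔ 7.0 counts/min) is internally consistent while walking rows
need not be.

## The PAL regression layer

Doubly-labeled-water TEE and ventilated-hood BMR enter as plain numbers;
`compute_pal()` forms their ratio (with a plausibility warning outside
1.1–2.6). Two published prediction equations ship as package defaults,
with predictors in counts/day to match their $10^{-5}$-scale slopes:

* simple: $\widehat{\mathrm{PAL}} = 1.24 + 9.70\times10^{-5} \cdot
  \text{activity counts}$,
* multiple: $\widehat{\mathrm{PAL}} = 1.17 + 10.92\times10^{-5} \cdot
  \text{nonwalking} + 13.42\times10^{-5} \cdot \text{short-walk}$.

`fit_pal_model()` is ordinary least squares reporting $r^2$, the
standard error of the estimate (residual SD with $n-p-1$ denominator),
coefficient SDs, standardized betas and p-values.
`stepwise_select()` is the classic p-value stepwise procedure (entry
$p<0.05$, removal $p>0.10$, both configurable) written explicitly
because AIC-based selection is a different rule. One known property of
forward selection worth stating: a pure-noise candidate gets an entry
opportunity at *every* step, so its inclusion probability slightly
exceeds the nominal 5% level — on simulated cohorts of 31 with two true
predictors and one noise predictor, the exact-recovery rate is about
93%, not 95%.

## What the synthetic generator emulates — and what it does not

The generators exist so that every stage has ground truth:

* `simulate_walk()` — vertical axis = 1 g + harmonic series at the step
  frequency (default 1.8 Hz, fundamental amplitude 0.3 g, two harmonics
  at 0.5 and 0.25 relative amplitude), amplitude-modulated at the stride
  frequency by the step asymmetry (default 0.2, which is what makes the
  stride the true period), plus white sensor noise (SD 0.03 g).
  Horizontal axes are attenuated (0.5, 0.3), phase-shifted copies. A
  harmonic model keeps closed-form count oracles available and the
  detection difficulty controllable.
* `simulate_nonwalk()` — band-limited (0.3–8 Hz) aperiodic noise scaled
  so realized epoch counts hit a target intensity exactly in the mean
  (counts are linear in amplitude); default target 7 counts/min, the
  published non-walking intensity.
* `simulate_treadmill_session()` — four constant-speed blocks of 3 min;
  speed maps affinely to step frequency (1.2 + 0.15·speed Hz) and
  amplitude (0.05 + 0.06·speed g), so 3–6 km/h spans 1.65–2.1 Hz and
  0.23–0.41 g. Only monotonicity of this mapping matters.
* `simulate_day()` — concatenates scheduled segments (walk / nonwalk /
  worn-idle / device-off, the last as exact zeros to exercise non-wear
  detection separately from inactivity) and returns truth labels and a
  truth daily summary. The default random schedule mirrors the cohort
  composition (about one fifth of active time walking, ~80% of bouts
  under a minute) compressed to ~40 min so that hundreds of days stay
  cheap; the validation runs in the test suite use 200 such days.
* `simulate_cohort()` — summary-level cohorts: per-subject daily
  category times and intensities drawn from the published between-subject
  means and SDs (truncated at zero), day-to-day variation at 20% CV, and
  PAL generated from a chosen prediction model plus Gaussian noise
  (default SD 0.13). Used for parameter-recovery tests (default
  n = 31 subjects × 14 days, 200 replicates).

Passing these tests shows the pipeline recovers what the generator
encodes: quasi-periodic versus aperiodic movement at realistic
intensities and sensor noise. It does **not** show robustness to
features real data have and the generator lacks: orientation drift and
re-wearing, non-walking activities with strong periodicity (cycling),
pathological or very slow gait, device non-linearity, or template drift
across the two monitored weeks. The clean separation the generator
affords (epoch-level balanced accuracy near 1 in the end-to-end test at
default settings) is an upper bound, not a field estimate.

## Other numerical choices

* Trailing partial epochs are dropped, never padded (padding would bias
  SDs and counts); sample conservation is tested.
* Non-60 Hz input is linearly resampled to 60 Hz before epoching, so
  templates and epochs stay commensurate.
* SDs/SDcc use the population ($n$) denominator; the choice is absorbed
  by density calibration but fixed for reproducibility.
* All JSON artifacts (templates, likelihood models, PAL models,
  manifests) are written with 17 significant digits, which round-trips
  IEEE doubles exactly; model scores after a save/load cycle are
  bit-identical, so calibration and daily-life processing can run as
  separate invocations.
* Every fixed constant of the pipeline lives in `pipeline_config()` and
  nowhere else.
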