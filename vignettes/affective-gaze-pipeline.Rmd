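---
title: "Methods: from gaze samples to affective attentional bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gaze samples to affective attentional bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in **gazebias**: the task
design, the dwell-time extraction and quality-control rules, the scoring
conventions, the mixed-model suite, and the synthetic gaze generator that
makes all of it testable without participant data. It also records the
numerical conventions and default parameters, with rationale, so that every
choice with scientific consequences is stated in one place.

## 1. The task and its design constants

The paradigm is paired-image free viewing: on each 10-second trial two
images appear side by side on a 1280 × 1024 screen while gaze is recorded
at 60 Hz. The stimulus set holds 96 images — 16 positive, 16 negative and
64 neutral — paired into 48 trials: 16 positive–neutral, 16
negative–neutral and 16 neutral–neutral pairs.

`build_trial_lists()` follows the two-list procedure: one list of 48
randomly ordered neutral images, a second list of the remaining 16 neutral
plus all 32 emotional images in random order; trials are formed by
index-wise pairing, each pair's left/right assignment is random, and the
trial order is itself randomized. Every image is used exactly once.

```{r design}
library(gazebias)
images <- synthetic_image_set(seed = 1)
trials <- build_trial_lists(images, seed = 1)
dplyr::count(trials, condition)
```

`validate_stimulus_set()` runs the standard stimulus-set checks: one-way
between-category models for valence and arousal with all three pairwise
contrasts tested against the pooled error term (df = N − 3 = 93 for 96
images) under a Bonferroni correction over the 3 contrasts, plus the same
F test for any low-level feature columns, which must *not* differ between
categories.

## 2. Dwell-time extraction

Gaze samples are classified against two area-of-interest (AOI) rectangles
— by default `(32, 339, 608, 685)` and `(672, 339, 1248, 685)`, i.e. 576 ×
346 px images horizontally centered in each screen half. Rectangles are
**half-open** (`x0 <= x < x1`, `y0 <= y < y1`): an edge sample gets a
deterministic assignment and the two AOIs can never both claim a point.
Invalid (track-lost) samples are never in an AOI.

Dwell bins are maximal runs of successive same-AOI samples. A new bin
starts when the AOI changes, an off-AOI sample intervenes, or the time
since the previous valid sample reaches the gap threshold. The gap
threshold is 33 ms at clean 60 Hz recording (two or more missed sample
periods); 66 ms and 133 ms are the recognised dialects for recordings
with degraded timing precision. Bin duration is *last minus first member
timestamp* — so a single-sample bin has duration 0 — and only bins of at
least 100 ms (boundary inclusive) count toward dwell time.

A worked trace: left-AOI samples at t = 0, 17, 33 and 100 ms with the
33 ms rule give two bins — {0..33 ms, 3 samples, duration 33 ms} and
{100 ms, 1 sample, duration 0} — and both are then removed by the 100 ms
filter.

`compute_trial_dwell()` composes these rules into one row per trial:
left/right dwell, the emotional/neutral relabelling via the trial's
emotional side, the first-saccade latency (timestamp of the first valid
in-AOI sample), the per-trial valid-sample count, and a start-in-AOI flag
(first recorded sample already inside an AOI — evidence the trial began
mid-saccade or miscalibrated).

## 3. Quality control

`qc_exclude()` applies a two-pass cohort-level rule. First pass: the mean
and SD of first-saccade latency and of the per-trial sample count are
computed over **all trials of all participants pooled**. Second pass: a
trial is excluded when

* its first sample was already inside an AOI,
* its latency exceeds the cohort mean + 3 SD (trials that never entered
  an AOI count as slow), or
* its sample count falls below the cohort mean − 3 SD.

A participant is excluded when more than a third of their trials are
excluded. Two deliberate conventions: a zero-variance cohort statistic
excludes nothing on that criterion (the rule needs spread to define a
tail), and the sample count refers to *valid* samples by default
(`qc_thresholds(count_invalid = TRUE)` switches to all recorded samples).

## 4. Scores and small-sample statistics

* **Bias score** (per emotional trial): dwell on the emotional image
  divided by total dwell on both images; 0.5 = no bias. Trials with zero
  total dwell are undefined and dropped with a warning; neutral–neutral
  trials carry no emotional/neutral labels and never enter.
* **ERQ preference**: mean of the six reappraisal items minus mean of the
  four suppression items (1–7 Likert). Any missing or out-of-range item
  flags the participant with NA scores.
* **Fisher r-to-z** (`fisher_r_to_z_test()`): two independent
  correlations compared via
  z = (atanh r₁ − atanh r₂) / √(1/(n₁−3) + 1/(n₂−3)), two-tailed normal
  p-value.
* **Power** (`rm_interaction_power()`): the within-between interaction in
  a g-group × m-measurement design, under the Cohen convention
  f² = η²/(1−η²), λ = f²·N, df₁ = (g−1)(m−1), df₂ = (N−g)(m−1), evaluated
  with the noncentral F distribution. A sphericity-style λ = f²·N·m
  variant is available because the literature is not unanimous; the
  convention in use is always explicit in the call.

## 5. The model suite

All models are Gaussian linear mixed models with a subject random
intercept, fitted by maximum likelihood (`REML = FALSE`) with
sum-to-zero contrasts for fixed factors, so the type-III F lines are
marginal tests. Fixed-effect t tests and F tests use Satterthwaite
degrees of freedom (via lmerTest; where a backend cannot supply the
gradient-based Satterthwaite df, a residual-df fallback would be
labelled — the df values themselves are never acceptance-tested).
Continuous variables are z-scored **within each model's analysis subset**
(e.g. within controls for the control-group model), so coefficients are
standardized betas.

| model | data | fixed effects |
|---|---|---|
| `m1` | emotional pairs, one row per image per trial | emotion × pair × location |
| `m1b` | neutral–neutral pairs | location |
| `m2` | per-trial bias scores | BDI × condition |
| `m3_control`, `m3_mdd` | per group | age × condition × preference |
| `m4` | all participants | age × condition × preference × BDI |

The dependent variable for `m3`/`m4` defaults to per-trial dwell time on
the emotional image, with `dv = "bias"` as a configuration switch; the
source material alternates between the two phrasings, and the dwell DV is
the recorded design decision.

Follow-ups: `emmeans_over_range()` computes the condition contrast with
predictions averaged, equally weighted, over an integer grid of the BDI
range of each group (observed-value weighting is the configurable
alternative); `age_slopes_at_levels()` evaluates the age simple slope per
condition at the preference mean plus {−1.5, −1, 0, +1, +1.5} SD, with
Satterthwaite t tests throughout (`emmeans` with
`lmer.df = "satterthwaite"`).

```{r models}
cohort <- generate_cohort(44, 28, seed = 1)
sim <- simulate_cohort_gaze(cohort, seed = 2)
dwell <- compute_trial_dwell(sim$samples, sim$trials)
kept <- qc_exclude(dwell)$kept
suite <- run_model_suite(kept, cohort)
age_slopes_at_levels(suite$m3_control)
```

## 6. The synthetic gaze generator

The generator is a **semi-Markov process**: after a truncated-normal
first-saccade latency (mean 310 ms, SD 250 ms — the cohort scale at which
the QC thresholds operate), gaze alternates between the two AOIs in
gamma-distributed episodes (shape 2, mean 600 ms), with a 0.1 probability
at each boundary of an off-AOI gap episode at the fixation cross. At each
episode boundary the emotional AOI is chosen with probability
`plogis(eta)`, where eta sums a baseline, the condition offset,
standardized age/preference/BDI terms and a subject random intercept.
Because episode durations are independent of the chosen side, the
long-run emotional dwell share equals `plogis(eta)` **exactly**, which is
what makes every planted effect recoverable in closed form — the central
design property of the generator.

Default planted coefficients (chosen once, as the study conditions for
all tests, before any recovery test was run): `b_pos = 0.3`,
`b_neg = 0.1`, `b_agexpref_pos = 0.15`, `b_agexpref_neg = −0.12`,
`b_bdi_neg = 0.2`, subject intercept SD 0.2. These mirror the qualitative
pattern the pipeline is designed to detect — an overall bias stronger for
positive pairs, an age-by-preference moderation of opposite sign in the
two emotional conditions, and a negativity bias scaling with depressive
symptoms. The episode scale (shape 2 / mean 600 ms) and off-AOI rate are
not taken from any source; they are realistic fixation-cluster values
chosen by this package.

Trait sampling mirrors the study population: ages 35–75; control BDI 0–8
(mean 1.8, SD 1.9), MDD BDI 10–47 (mean 27.3, SD 9.3), both truncated
normal rounded to integers; ERQ items from a latent bivariate normal per
subject with a −0.476 reappraisal–suppression correlation and a positive
reappraisal preference in controls, zero correlation and no preference in
the MDD group.

`inject_artifacts()` degrades clean streams with the failure modes QC is
built to catch — per-sample dropout, start-in-AOI trials, slow-latency
trials and truncated trials — and returns a ground-truth manifest. The
forced-slow-latency default is 3000 ms: because the QC cutoff is
data-derived, the artifact must sit far enough outside the
contamination-inflated mean + 3 SD band to be provably caught at
realistic (≤ 10%) contamination rates; 3000 ms models a gross tracking
failure and satisfies that arithmetic with a wide margin.

What the generator deliberately does **not** emulate: saccade
trajectories and velocity profiles (samples jump between fixation
clusters), pupil data, drift or calibration decay over the session,
image-content salience within an AOI, and any dependence of episode
length on the viewed image. It is a generator for testing the *pipeline*,
not a model of oculomotor behaviour.

## 7. Reproducibility and I/O conventions

All tables are written as TSV with `#`-prefixed provenance headers
(package version, seed, config hash); TSV avoids locale decimal-comma
ambiguity, and all times in files are milliseconds. `run_pipeline()`
chains simulate → preprocess → score → analyze → report under one YAML
configuration and seed; re-running a configuration reproduces its outputs
byte-for-byte. Every stochastic function takes an explicit seed and
restores the caller's RNG state.

## 8. Test problem sizes

The replicate-based test suites run at sizes chosen by this package for a
single-CPU budget: the QC ground-truth check uses a 50-subject cohort at
1% dropout and 3% per-trial artifact rates; null-model type-I calibration
uses 200 replicate fits of 50 subjects × 10 observations, with the
rejection count required to stay inside the two-sided 99.9% binomial band
around α = 0.05; planted-moderation sign recovery uses 50 replicates of a
24-subject cohort through the full simulate → extract → fit path,
requiring the age slope at +1 SD preference in the positive condition to
be positive in at least 80% of replicates.

## 9. Limitations

* The mixed-model F statistics of any particular real dataset are not
  reproducible from summary statistics alone; the suite therefore tests
  worked examples, closed-form oracles and recovery of planted structure,
  not numerical replication of published tables.
* Satterthwaite approximations can be anti-conservative for very small
  cohorts; the singular-fit and convergence flags on `gazebias_fit`
  objects should be checked before interpreting boundary fits.
* The bias score is undefined for zero-dwell trials; cohorts with heavy
  track loss lose trials at scoring as well as at QC.
* The generator's stationarity means it cannot produce time-course
  effects (e.g. early vigilance, late avoidance); analyses of dwell by
  time window would need a different generator.
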