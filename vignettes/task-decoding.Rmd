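---
title: "Decoding viewing task from aggregate eye-movement features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding viewing task from aggregate eye-movement features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When people read, skim pseudo-text, search a scene, or memorize a scene,
the temporal statistics of their eye movements change: reading is built
from short fixations and small, regular saccades; scene viewing from
longer fixations and larger saccades; memorization from longer and more
variable fixations than search over the same images. None of these
measures is diagnostic on its own — the distributions overlap heavily —
but jointly they may carry enough information to infer the viewer's task
from a single 12-second trial.

`gazetask` implements that inference pipeline end to end and, because raw
eye-tracking recordings of this design are not publicly deposited, pairs
it with a seeded synthetic cohort generator so every stage can be tested
against known ground truth.

## The model, stage by stage

### Synthetic cohort generator

A cohort is the full factorial of 12 participants x 2 sessions (labelled
`day1` and `day3`) x 4 tasks, with per-session trial counts 40 (scene
memorization), 35 (reading), 48 (scene search) and 35 (pseudo-reading).
A trial alternates fixations and saccades, starting with a fixation,
until the cumulative event time first reaches the 12,000 ms viewing
budget (saccade durations enter the budget through the main-sequence
approximation `21 + 2.2 * amplitude` ms).

Fixation durations are drawn from a task-specific **ex-Gaussian**
distribution — the convolution of a Normal(mu, sigma) and an Exponential
with mean tau, the standard three-parameter family for right-skewed
duration distributions. Saccade amplitudes are drawn from a task-specific
**gamma** distribution (right-skewed, positive support), a choice made
here because the pipeline itself never models amplitudes beyond their
mean and SD.

Two artifact processes mirror what real fixation reports contain: with
probability `blink_prob` (default 0.02) a blink follows a fixation,
flagging it and the next saccade as blink-adjacent; with probability
`long_fix_prob` (default 0.005) a fixation duration is replaced by an
artifactual value in (1501, 3000) ms. Search trials carry a target with
probability 2/3 and, when present, the target is found with probability
0.85; found trials are generated at full length and excluded later, in
preprocessing, which keeps generation uniform.

**Random effects.** Individuals differ, and the same individual differs
between days. Both are modelled as additive Normal offsets on mu and tau
of the fixation-duration distribution and on the log of the gamma
amplitude scale. Participant effects (SDs 15 ms, 12 ms, 0.10) are drawn
once per participant and persist across sessions; session effects are
drawn independently for every participant x session x **task**. Drawing
the session drift per task, rather than one draw shared by a whole
session, reflects the view that what changes between days is largely
task engagement and strategy rather than a global shift of the
oculomotor system, and it makes the cohort-level cross-session accuracy
a much more stable function of the seed (one shared draw per session
left the cohort mean at the mercy of ~24 random numbers).

**Calibration.** The shipped task profiles and the session-drift SDs
(14.7 ms on mu, 11 ms on tau, 0.059 on log amplitude scale) are
calibration values, not estimates of any real population: they were
chosen once so that the pipeline reproduces the qualitative regime of
interest — within-session four-way decoding in the mid-80s percent,
cross-session decoding near 68%, both far above the 25% chance level —
and then frozen. Mean fixation durations (mu + tau) span roughly
280-330 ms across tasks and mean saccade amplitudes roughly 2.3-4.0
degrees, with reading at the short-and-small corner and the scene tasks
at the long-and-large corner, search slightly faster-paced than
memorization.

### Preprocessing

Three exclusion rules are applied before any feature is computed:

1. fixations strictly longer than 1500 ms are removed ("longer than" is
   read literally: a fixation of exactly 1500 ms is kept);
2. events flagged as immediately preceding or following a blink are
   removed — only the directly flagged events, not their further
   neighbours;
3. search trials on which the target was found are removed, because the
   button press truncates the recording.

All three are pure row subsets, so they are idempotent, order-preserving
and mutually commuting, properties the test suite asserts directly.
Trials left with fewer than 2 fixations or 2 saccades are dropped with a
logged count, since a standard deviation needs at least two
observations.

### Features

Each surviving trial is summarized by either four features — mean and SD
of fixation duration, mean and SD of saccade amplitude (SDs use the n-1
denominator) — or eight, appending the number of fixations and the three
ex-Gaussian parameters fitted to the trial's fixation durations.

Two ex-Gaussian estimators are provided. The default is direct maximum
likelihood: L-BFGS-B from a moment-based start (tau0 from the sample
skewness, clamped to [0.05, 0.95] of the sample SD; mu0 = mean - tau0;
sigma0 from the residual variance), with sigma and tau bounded below by
1e-3 ms so the optimizer cannot collapse onto the boundary. The
alternative is a quantile-based maximum-probability estimator in the
style of the tools long used for response-time distributions: the sample
is split at its deciles and the parameters maximize the multinomial
probability of the inter-quantile counts. MLE is the pipeline default
because it is deterministic given the data and slightly more efficient
at trial-sized samples; the tests require the two estimators to agree
within 10% on clean data.

The density is evaluated in log space with `pnorm(..., log.p = TRUE)`;
for tau < 0.05 sigma the analytic form suffers catastrophic cancellation
and the code switches to the Normal limit. A trial needs at least 8
fixations for the fit; eight-feature analyses drop (and count) trials
below that.

### Classifier

The classifier is Gaussian naive Bayes, written out in full rather than
wrapped from a library, because its exact conventions are the modelling
core of the pipeline: empirical class priors (the design is unbalanced
by construction and search-trial removal makes it more so; uniform
priors are available by flag), per-class per-feature Gaussian
likelihoods with maximum-likelihood (n-denominator) variances, and a
per-feature variance floor of 1e-9 times the global feature variance to
keep degenerate folds finite. Exact posterior ties break
deterministically to the class that comes first in the fixed order
(pseudo-reading, reading, scene memorization, scene search). The
independence assumption is knowingly false — mean fixation duration and
the fitted mu + tau are strongly correlated — which is the usual naive
Bayes bargain.

Within-session evaluation is leave-one-out cross-validation. The
per-fold model is obtained by downdating the class sums and sums of
squares, which is algebraically identical to refitting on the n-1
remaining trials (the test suite checks every fold against an explicit
refit) and turns LOOCV into an O(n) pass cheap enough to sit inside a
permutation loop. The variance floor is computed once from the full
matrix so all folds share it. Cross-session evaluation fits one session
and tests the other, both directions, never pooling sessions. Accuracy
is the proportion of correctly classified trials; confusion matrices are
row-normalized (row = true class).

### Significance

Observed accuracies are judged against an empirical null distribution:
2000 (by default) re-runs of the full classification scheme with
uniformly permuted training labels, test labels untouched. Under LOOCV,
one permutation of the full label vector is drawn per iteration and each
fold trains on the permuted labels of its training portion — the natural
reading of "permuting labels in the training set" that keeps every
iteration internally consistent. The p-value is the add-one estimator
(1 + #{null >= observed}) / (1 + n_perm), never exactly zero, with ties
counted against rejection; the decision level is .05.

## What the defaults mean

| parameter | default | units | why |
|---|---|---|---|
| `trial_budget_ms` | 12000 | ms | trial length of the emulated design |
| `trials_per_task` | 40/35/48/35 | trials | memorization/reading/search/pseudo per session |
| `target_present_prob` | 2/3 | — | one third of search scenes lack a target |
| `target_found_prob` | 0.85 | — | most present targets are found within 12 s |
| `blink_prob` | 0.02 | per fixation | a blink every ~50 fixations |
| `long_fix_prob` | 0.005 | per fixation | rare tracker artifacts above 1500 ms |
| `max_ms` (long-fixation cutoff) | 1500 | ms | conventional artifact threshold, strict |
| `min_n` (ex-Gaussian fit) | 8 | fixations | below this a 3-parameter fit is meaningless |
| `n_perm` | 2000 | — | resolution ~5e-4 for the add-one p-value |
| `alpha` | .05 | — | decision level |
| variance floor | 1e-9 x global | — | guards degenerate folds only |

## What the synthetic cohort does and does not show

The generator reproduces the *statistical skeleton* the analysis relies
on: task-conditional ex-Gaussian durations, right-skewed amplitudes,
stable individual differences, session drift, artifact contamination,
and the exact factorial design and trial budget. It deliberately omits
much of what makes real data hard: gaze location and stimulus content,
serial dependence within a trial (events are i.i.d. given the trial's
parameters), word-by-word reading dynamics, pupil measures, and any
non-stationarity within a session. Passing tests on this cohort
therefore certify the pipeline — the filters, estimators, classifier and
test are correct and well calibrated — not that real eye movements are
decodable at any particular accuracy; published accuracies from real
cohorts of this design are the external anchor for that.

Problem sizes in the tests and the acceptance script are chosen at desk
scale: the full 12-participant cohort (~3,100 analyzed trials) for the
decoding estimates, 500 permutations for the chance baseline, and 200
replicates x 200 permutations for the type-I-error check.

## Numerical choices and degenerate inputs

* `dexgauss`/`pexgauss` switch to the Normal limit below tau/sigma =
  0.05; both estimators bound sigma, tau >= 1e-3.
* Generated fixation durations are floored at 10 ms (tracker parsers do
  not emit shorter events); effect-adjusted tau is clamped at 1 ms with
  a warning.
* Non-convergence of the ex-Gaussian optimizer is flagged in the fit's
  attributes rather than silently accepted.
* A class with fewer than 2 (fit) or 3 (LOOCV) trials is an error, not a
  silent degenerate fit; `run_experiment` logs such cells and continues.
* Ties in the posterior break by fixed class order, making every result
  exactly reproducible.

## Known limitations

* Trial-level ex-Gaussian fits from ~20-40 fixations are noisy by
  nature; the eight-feature representation gains from them mainly
  because naive Bayes tolerates noisy, redundant features.
* The permutation scheme draws its null independently per model run;
  nothing is shared across participants.
* The generator's parameters are calibration knobs. Fitting them to a
  real fixation report (the CSV dialect is designed for that) is the
  intended route to realism, not adjusting them by hand.
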