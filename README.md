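# gazetask

Decoding a viewer's task from the aggregate statistics of their eye
movements.

## The problem

Fixation durations and saccade amplitudes are shaped by what a viewer is
doing: reading proceeds in short fixations and small, regular saccades;
searching or memorizing a scene in longer fixations and larger
saccades. No single measure separates the tasks — their distributions
overlap heavily — but a trial's joint summary statistics may still
identify the task. `gazetask` implements the full decoding pipeline for
four tasks (reading, pseudo-reading, scene search, scene memorization)
and pairs it with a seeded synthetic cohort generator, so that every
stage can be validated against known ground truth even though raw
recordings of this design are not publicly available.

The pipeline, per trial and participant:

1. **Preprocess** a fixation-report event table: remove fixations
   longer than 1500 ms, events adjacent to blinks, and search trials on
   which the target was found.
2. **Summarize** each trial by four features — mean and SD of fixation
   duration, mean and SD of saccade amplitude — or eight, adding the
   number of fixations and the three parameters (mu, sigma, tau) of an
   **ex-Gaussian** distribution fitted to the trial's fixation
   durations (Normal(mu, sigma) convolved with an Exponential of mean
   tau; fitted by bounded maximum likelihood or by a quantile-based
   maximum-probability estimator).
3. **Classify** with Gaussian naive Bayes: for class k and feature
   vector x, the posterior is p(k | x) proportional to
   `pi_k * prod_j N(x_j; mu_kj, sigma_kj^2)`, with empirical priors
   pi_k and maximum-likelihood per-class variances. Within-session
   performance uses leave-one-out cross-validation; cross-session
   performance trains on one day and tests on the other.
4. **Test significance** against an empirical null: the scheme is re-run
   on permuted training labels (2000 permutations by default) and the
   observed accuracy gets the add-one p-value
   `(1 + #{null >= observed}) / (1 + n_perm)`, evaluated at .05.

## Worked example

```r
library(gazetask)

# a small cohort: 4 participants, 2 sessions, reduced trial counts
cfg <- cohort_config(
  n_participants = 4,
  trials_per_task = c(pseudo_reading = 12, reading = 12,
                      scene_memorization = 12, scene_search = 18),
  rng_seed = 9)
events <- preprocess_events(generate_cohort(cfg))
feats <- feature_table(events, mode = "eight")

# within-session decoding for participant p01, day 1
sub <- feats[feats$participant == "p01" & feats$session == "day1", ]
res <- loocv(feature_matrix(sub), sub$task, class_order = gaze_tasks())
res
#> classification result: accuracy 0.872 over 47 trials
round(res$confusion, 2)
#>                     predicted
#> true                 pseudo_reading reading scene_memorization scene_search
#>   pseudo_reading               0.92    0.08               0.00         0.00
#>   reading                      0.08    0.92               0.00         0.00
#>   scene_memorization           0.00    0.00               0.92         0.08
#>   scene_search                 0.00    0.00               0.27         0.73

# is 87% significant against chance (~25%)?
pt <- permutation_null(feature_matrix(sub), sub$task, scheme = "loocv",
                       n_perm = 500, seed = 1, class_order = gaze_tasks())
pt
#> permutation test (loocv): observed accuracy 0.872, null mean 0.247 (500 permutations)
#>   p = 0.001996; reject at alpha = 0.05
```

The accuracy (0.872) is the proportion of the 47 trials whose task the
classifier identified from held-out data. The confusion matrix shows the
expected structure: the two text-like tasks confuse only with each
other, and the hardest pair is search versus memorization — the two
tasks performed over identical scene stimuli. The permutation p-value
1/501 says no permuted-label re-run came close to 87%.

The full study-scale analysis lives in `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R     # default 12-participant cohort
Rscript analysis/02_preprocess_features.R
Rscript analysis/03_within_session.R      # LOOCV, all designs and modes
Rscript analysis/04_cross_session.R       # day1 <-> day3 transfer
Rscript analysis/05_significance.R        # permutation tests
```

Each script prints a short narrative and writes its tables under
`results/`. On the shipped default cohort the four-task, eight-feature
analysis lands in the mid-80s percent within session and near 68%
across sessions, against a 25% chance level — the cross-session drop is
produced by the generator's session-level drift in each task's
parameters.

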