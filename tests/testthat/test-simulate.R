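# Synthetic cohort generator: design fidelity, stopping rule, artifact
# injection, random-effect structure and reproducibility.

test_that("trials alternate events and stop exactly at the budget", {
  profile <- default_task_profiles()$reading
  set.seed(1)
  for (rep in 1:20) {
    tr <- sample_trial(profile, budget_ms = 12000)
    expect_identical(tr$event_type,
                     rep(c("fixation", "saccade"),
                         length.out = nrow(tr)))
    expect_identical(tr$event_index, seq_len(nrow(tr)) - 1L)
    # total event time first reaches the budget at the last event
    dur <- ifelse(tr$event_type == "fixation", tr$duration_ms,
                  21 + 2.2 * tr$amplitude_deg)
    expect_gte(sum(dur), 12000)
    expect_lt(sum(dur) - dur[length(dur)], 12000)
  }
})

test_that("artifact injection follows the configured probabilities", {
  profile <- default_task_profiles()$scene_search
  set.seed(2)
  tr <- sample_trial(profile, long_fix_prob = 1)
  expect_true(all(tr$duration_ms[tr$event_type == "fixation"] > 1500))
  tr0 <- sample_trial(profile, blink_prob = 0, long_fix_prob = 0)
  expect_false(any(tr0$blink_before | tr0$blink_after))
  expect_true(all(tr0$duration_ms[tr0$event_type == "fixation"] <= 1500))
  # a blink flags the fixation it follows and the saccade it precedes
  tr1 <- sample_trial(profile, blink_prob = 1)
  expect_true(all(tr1$blink_after[tr1$event_type == "fixation"]))
  expect_true(all(tr1$blink_before[tr1$event_type == "saccade"]))
})

test_that("generated fixation durations follow the configured ex-Gaussian", {
  # pooled draws with zero random effects and no artifact injection pass
  # a goodness-of-fit test against the generating distribution
  profile <- default_task_profiles()$scene_memorization
  set.seed(3)
  dur <- c()
  while (length(dur) < 1e4) {
    tr <- sample_trial(profile, blink_prob = 0, long_fix_prob = 0)
    dur <- c(dur, tr$duration_ms[tr$event_type == "fixation"])
  }
  p <- profile$fixdur_params
  ks <- suppressWarnings(stats::ks.test(
    dur[seq_len(1e4)], function(q) pexgauss(q, p$mu, p$sigma, p$tau)))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort matches the configured factorial design exactly", {
  cfg <- small_cohort(seed = 4)
  ev <- generate_cohort(cfg)
  counts <- with(unique(ev[c("participant", "session", "task", "trial")]),
                 table(participant, session, task))
  for (p in dimnames(counts)$participant)
    for (s in dimnames(counts)$session)
      for (tk in names(cfg$trials_per_task))
        expect_equal(counts[p, s, tk],
                     unname(cfg$trials_per_task[tk]),
                     ignore_attr = TRUE)
  # participant/session/task key structure
  expect_setequal(unique(ev$session), c("day1", "day3"))
  expect_setequal(unique(ev$task), gaze_tasks())
})

test_that("search trials carry target flags at the configured rates", {
  cfg <- cohort_config(n_participants = 6, rng_seed = 8)
  ev <- generate_cohort(cfg)
  tr <- unique(ev[c("participant", "session", "task", "trial",
                    "target_present", "target_found")])
  search <- tr[tr$task == "scene_search", ]
  other <- tr[tr$task != "scene_search", ]
  expect_true(all(is.na(other$target_present)))
  expect_true(all(!is.na(search$target_present)))
  # about one third of search trials lack a target (binomial 3 SE band)
  p_absent <- mean(!search$target_present)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(search))
  expect_lt(abs(p_absent - 1 / 3), 3 * se)
  # the target can only be found when present
  expect_true(all(!search$target_found[!search$target_present]))
})

test_that("equal seeds give identical cohorts, different seeds differ", {
  cfg <- small_cohort(seed = 5)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- small_cohort(seed = 6)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- stats::runif(3)
  set.seed(123)
  invisible(generate_cohort(small_cohort(seed = 7, n_participants = 1)))
  b <- stats::runif(3)
  expect_identical(a, b)
})

test_that("session effects separate sessions; zero SDs do not", {
  base <- cohort_config(
    n_participants = 4,
    trials_per_task = c(pseudo_reading = 12, reading = 12,
                        scene_memorization = 12, scene_search = 12),
    blink_prob = 0, long_fix_prob = 0, rng_seed = 9)
  drifted <- base
  still <- base
  still$session_sd <- c(mu = 0, tau = 0, log_scale = 0)
  sess_gap <- function(cfg) {
    ev <- generate_cohort(cfg)
    fx <- ev[ev$event_type == "fixation" & ev$task == "reading", ]
    m <- tapply(fx$duration_ms, list(fx$participant, fx$session), mean)
    mean(abs(m[, "day1"] - m[, "day3"]))
  }
  # with drift the per-session means move far beyond sampling error;
  # without drift they agree within it (~ sd/sqrt(n) a few ms)
  expect_gt(sess_gap(drifted), 8)
  expect_lt(sess_gap(still), 8)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(cohort_config(blink_prob = 1.5), "probabilities")
  expect_error(cohort_config(trials_per_task = c(reading = 0)), "profile|>= 1")
  expect_error(cohort_config(trial_budget_ms = -1))
  expect_error(task_profile("reading", exgauss_params(200, 40, 70),
                            saccamp_shape = -1, saccamp_scale = 0.4),
               "shape")
})

test_that("a cohort configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_participants: 3",
    "rng_seed: 21",
    "blink_prob: 0.0",
    "trials_per_task:",
    "  reading: 5",
    "  pseudo_reading: 5",
    "  scene_memorization: 5",
    "  scene_search: 5",
    "task_profiles:",
    "  reading: {mu: 210, sigma: 40, tau: 70, saccamp_shape: 6, saccamp_scale: 0.4}",
    "  pseudo_reading: {mu: 225, sigma: 45, tau: 95, saccamp_shape: 6, saccamp_scale: 0.45}",
    "  scene_memorization: {mu: 220, sigma: 55, tau: 110, saccamp_shape: 6, saccamp_scale: 0.6}",
    "  scene_search: {mu: 190, sigma: 50, tau: 85, saccamp_shape: 6, saccamp_scale: 0.66}"
  ), path)
  cfg <- cohort_config_from_yaml(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_participants, 3L)
  expect_equal(cfg$blink_prob, 0)
  expect_equal(cfg$task_profiles$reading$fixdur_params$mu, 210)
  ev <- generate_cohort(cfg)
  expect_equal(length(unique(ev$participant)), 3)
})
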