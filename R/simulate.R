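# Synthetic cohort generator: seeded fixation/saccade event streams with the
# statistical structure the downstream analysis assumes. Trials alternate
# fixations and saccades until a 12-s viewing budget is spent; fixation
# durations follow task-specific ex-Gaussian distributions and saccade
# amplitudes task-specific gamma distributions, perturbed by participant- and
# session-level random effects.

#' Task-specific generating profile
#'
#' Distributional profile of one viewing task: an ex-Gaussian fixation
#' duration distribution and a gamma saccade amplitude distribution
#' (right-skewed, positive support, mean `shape * scale` degrees).
#'
#' @param task_label One of `"reading"`, `"pseudo_reading"`,
#'   `"scene_search"`, `"scene_memorization"`.
#' @param fixdur_params An [exgauss_params()] object (ms).
#' @param saccamp_shape,saccamp_scale Gamma shape (dimensionless) and scale
#'   (degrees) of the saccade amplitude distribution; both positive.
#' @return An object of class `task_profile`.
#' @export
task_profile <- function(task_label, fixdur_params, saccamp_shape,
                         saccamp_scale) {
  task_label <- match.arg(task_label, gaze_tasks())
  stopifnot(inherits(fixdur_params, "exgauss_params"))
  if (saccamp_shape <= 0 || saccamp_scale <= 0)
    stop("task_profile: gamma shape and scale must be > 0", call. = FALSE)
  structure(list(task_label = task_label, fixdur_params = fixdur_params,
                 saccamp_shape = saccamp_shape, saccamp_scale = saccamp_scale),
            class = "task_profile")
}

#' Canonical task labels
#'
#' The four viewing tasks, in the fixed order used for classifier
#' tie-breaking and confusion matrix rows.
#'
#' @return Character vector of length four.
#' @export
gaze_tasks <- function() {
  c("pseudo_reading", "reading", "scene_memorization", "scene_search")
}

#' Shipped task calibration profiles
#'
#' Default generating profiles for the four tasks. These are calibration
#' values chosen to reproduce the qualitative structure of task-evoked
#' eye movements -- short fixations and small saccades in reading, larger
#' saccades over scenes, longer and more variable fixations in
#' memorization -- with enough overlap that classification is hard but
#' far above chance. They are configuration, not estimates of any
#' particular participant population.
#'
#' @return Named list of [task_profile()] objects.
#' @export
default_task_profiles <- function() {
  list(
    reading = task_profile("reading",
      exgauss_params(mu = 206, sigma = 40, tau = 76),
      saccamp_shape = 6, saccamp_scale = 0.392),
    pseudo_reading = task_profile("pseudo_reading",
      exgauss_params(mu = 220, sigma = 45, tau = 94),
      saccamp_shape = 6, saccamp_scale = 0.444),
    scene_search = task_profile("scene_search",
      exgauss_params(mu = 196, sigma = 50, tau = 87),
      saccamp_shape = 6, saccamp_scale = 0.648),
    scene_memorization = task_profile("scene_memorization",
      exgauss_params(mu = 217, sigma = 55, tau = 108),
      saccamp_shape = 6, saccamp_scale = 0.590)
  )
}

#' Cohort design configuration
#'
#' Full description of a synthetic cohort: its factorial design
#' (participants x sessions x tasks x trials), the task generating
#' profiles, the random-effect scales and the artifact injection rates.
#' Defaults mirror a 12-participant, 2-session design with per-session
#' trial counts 40 (memorization) / 35 (reading) / 48 (search) /
#' 35 (pseudo-reading), 12-second trials, and one third of search trials
#' lacking a target.
#'
#' Random effects are additive offsets on mu and tau of the fixation
#' duration distribution and on the log of the gamma saccade amplitude
#' scale. Participant effects are drawn once per participant and persist
#' across that participant's sessions; session effects are drawn
#' independently for every participant x session x task (task engagement
#' drifts between days in a task-specific way), so the two sessions of
#' the same participant differ, which is what degrades cross-session
#' relative to within-session classification.
#'
#' @param n_participants,n_sessions Design counts (defaults 12 and 2).
#' @param trials_per_task Named integer vector, trials per task per session.
#' @param trial_budget_ms Viewing time per trial (default 12000 ms).
#' @param task_profiles Named list of [task_profile()] objects.
#' @param participant_sd,session_sd Named numeric vectors with elements
#'   `mu`, `tau` (ms) and `log_scale` (log degrees): SDs of the
#'   corresponding random-effect offsets.
#' @param blink_prob Probability that a blink follows any given fixation,
#'   flagging that fixation and the next saccade as blink-adjacent.
#' @param long_fix_prob Probability a fixation duration is replaced by an
#'   artifactual value above 1500 ms.
#' @param target_present_prob Probability a search trial contains a target
#'   (default 2/3).
#' @param target_found_prob Probability the target is found given present.
#' @param rng_seed Integer seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 12,
                          n_sessions = 2,
                          trials_per_task = c(pseudo_reading = 35,
                                              reading = 35,
                                              scene_memorization = 40,
                                              scene_search = 48),
                          trial_budget_ms = 12000,
                          task_profiles = default_task_profiles(),
                          participant_sd = c(mu = 15, tau = 12,
                                             log_scale = 0.10),
                          session_sd = c(mu = 14.7, tau = 11,
                                         log_scale = 0.059),
                          blink_prob = 0.02,
                          long_fix_prob = 0.005,
                          target_present_prob = 2 / 3,
                          target_found_prob = 0.85,
                          rng_seed = 1L) {
  stopifnot(n_participants >= 1, n_sessions >= 1, trial_budget_ms > 0)
  if (is.null(names(trials_per_task)) ||
      !all(names(trials_per_task) %in% gaze_tasks()))
    stop("cohort_config: trials_per_task must be named by task", call. = FALSE)
  if (any(trials_per_task < 1))
    stop("cohort_config: all trial counts must be >= 1", call. = FALSE)
  if (!all(names(trials_per_task) %in% names(task_profiles)))
    stop("cohort_config: every task needs a profile", call. = FALSE)
  probs <- c(blink_prob, long_fix_prob, target_present_prob, target_found_prob)
  if (any(probs < 0 | probs > 1))
    stop("cohort_config: probabilities must lie in [0, 1]", call. = FALSE)
  for (nm in c("mu", "tau", "log_scale")) {
    if (is.na(participant_sd[nm]) || is.na(session_sd[nm]))
      stop(sprintf("cohort_config: random-effect SDs need element '%s'", nm),
           call. = FALSE)
  }
  if (any(participant_sd < 0) || any(session_sd < 0))
    stop("cohort_config: random-effect SDs must be >= 0", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions),
    trials_per_task = trials_per_task,
    trial_budget_ms = trial_budget_ms,
    task_profiles = task_profiles,
    participant_sd = participant_sd,
    session_sd = session_sd,
    blink_prob = blink_prob,
    long_fix_prob = long_fix_prob,
    target_present_prob = target_present_prob,
    target_found_prob = target_found_prob,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Scalar fields override the defaults of [cohort_config()]; task profiles
#' are given as `task_profiles: {reading: {mu: ..., sigma: ..., tau: ...,
#' saccamp_shape: ..., saccamp_scale: ...}, ...}`.
#'
#' @param path YAML file.
#' @return A [cohort_config()] object.
#' @export
cohort_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$trials_per_task))
    args$trials_per_task <- unlist(raw$trials_per_task)
  for (nm in c("participant_sd", "session_sd"))
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$task_profiles)) {
    args$task_profiles <- lapply(names(raw$task_profiles), function(tk) {
      p <- raw$task_profiles[[tk]]
      task_profile(tk, exgauss_params(p$mu, p$sigma, p$tau),
                   p$saccamp_shape, p$saccamp_scale)
    })
    names(args$task_profiles) <- names(raw$task_profiles)
  }
  do.call(cohort_config, args)
}

# Saccade durations only matter for the trial time budget; approximate the
# main-sequence relation between amplitude and duration.
.saccade_duration_ms <- function(amplitude_deg) {
  21 + 2.2 * amplitude_deg
}

# Apply additive random-effect offsets to a task profile, clamping tau and
# the gamma scale to positive floors (warning when a clamp fires).
.apply_effects <- function(profile, effects) {
  mu <- profile$fixdur_params$mu + effects[["mu"]]
  tau <- profile$fixdur_params$tau + effects[["tau"]]
  scale <- profile$saccamp_scale * exp(effects[["log_scale"]])
  if (tau < 1) {
    warning("effect-adjusted tau below 1 ms; clamped", call. = FALSE)
    tau <- 1
  }
  list(mu = mu, sigma = profile$fixdur_params$sigma, tau = tau,
       shape = profile$saccamp_shape, scale = scale)
}

#' Simulate one trial of alternating fixations and saccades
#'
#' Events are appended, starting with a fixation, until the cumulative
#' event time (fixation durations plus main-sequence saccade durations)
#' first reaches or exceeds the viewing budget. Fixation durations are
#' drawn from the effect-adjusted ex-Gaussian, saccade amplitudes from the
#' effect-adjusted gamma. With probability `long_fix_prob` a fixation is
#' replaced by an artifactual duration above 1500 ms; with probability
#' `blink_prob` a blink follows a fixation, flagging it (`blink_after`)
#' and the following saccade (`blink_before`).
#'
#' @param profile A [task_profile()].
#' @param budget_ms Positive viewing budget.
#' @param effects Named numeric offsets (`mu`, `tau`, `log_scale`);
#'   defaults to zero.
#' @param blink_prob,long_fix_prob Injection probabilities.
#' @return A data.frame of events with `event_index` from 0, alternating
#'   `fixation`/`saccade` rows.
#' @export
sample_trial <- function(profile, budget_ms = 12000,
                         effects = c(mu = 0, tau = 0, log_scale = 0),
                         blink_prob = 0, long_fix_prob = 0) {
  if (budget_ms <= 0) stop("sample_trial: budget_ms must be > 0", call. = FALSE)
  par <- .apply_effects(profile, effects)
  # Draw in blocks: expected events per 12 s is ~70, so one block usually
  # suffices; top up if the budget is not yet spent.
  dur <- numeric(0); amp <- numeric(0)
  n_need <- ceiling(budget_ms / (par$mu + par$tau + 30)) + 8
  repeat {
    dur <- c(dur, rexgauss(n_need, par$mu, par$sigma, par$tau))
    amp <- c(amp, stats::rgamma(n_need, shape = par$shape, scale = par$scale))
    dur[dur < 10] <- 10  # tracker parsers do not emit sub-10-ms fixations
    long <- stats::runif(length(dur)) < long_fix_prob
    dur2 <- ifelse(long, stats::runif(length(dur), 1501, 3000), dur)
    # interleave fix, sacc, fix, sacc, ...
    times <- as.vector(rbind(dur2, .saccade_duration_ms(amp)))
    if (sum(times) >= budget_ms) {
      n_events <- which(cumsum(times) >= budget_ms)[1]
      break
    }
    n_need <- ceiling(n_need / 2) + 4
  }
  n_fix <- ceiling(n_events / 2)
  n_sacc <- floor(n_events / 2)
  dur2 <- dur2[seq_len(n_fix)]
  amp <- amp[seq_len(n_sacc)]
  blink_after_fix <- stats::runif(n_fix) < blink_prob
  ev_type <- rep(c("fixation", "saccade"), length.out = n_events)
  out <- data.frame(
    event_index = seq_len(n_events) - 1L,
    event_type = ev_type,
    duration_ms = NA_real_,
    amplitude_deg = NA_real_,
    blink_before = FALSE,
    blink_after = FALSE,
    stringsAsFactors = FALSE
  )
  fix_rows <- which(ev_type == "fixation")
  sacc_rows <- which(ev_type == "saccade")
  out$duration_ms[fix_rows] <- dur2
  out$amplitude_deg[sacc_rows] <- amp
  out$blink_after[fix_rows] <- blink_after_fix
  follows <- fix_rows[blink_after_fix] + 1L
  follows <- follows[follows <= n_events]
  out$blink_before[follows] <- TRUE
  out
}

#' Generate a synthetic cohort of eye-movement event streams
#'
#' Produces the full factorial design of the configuration: for each
#' participant and session, exactly the configured number of trials per
#' task. Search trials carry `target_present` / `target_found` flags;
#' trials where the target was found are generated at full length and
#' excluded later in preprocessing. The result is a pure function of the
#' configuration, including its `rng_seed`.
#'
#' @param config A [cohort_config()].
#' @return A data.frame event table in the fixation-report dialect (one
#'   row per event; columns participant, session, task, trial,
#'   event_index, event_type, duration_ms, amplitude_deg, blink_before,
#'   blink_after, target_present, target_found).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$rng_seed)

  tasks <- names(config$trials_per_task)
  p_ids <- sprintf("p%02d", seq_len(config$n_participants))
  s_ids <- sprintf("day%d", 2L * seq_len(config$n_sessions) - 1L)
  pieces <- vector("list", 0L)
  for (pi in seq_along(p_ids)) {
    p_eff <- stats::rnorm(3, 0, config$participant_sd[c("mu", "tau",
                                                        "log_scale")])
    names(p_eff) <- c("mu", "tau", "log_scale")
    for (si in seq_along(s_ids)) {
      for (tk in tasks) {
        s_eff <- stats::rnorm(3, 0, config$session_sd[c("mu", "tau",
                                                        "log_scale")])
        names(s_eff) <- c("mu", "tau", "log_scale")
        eff <- p_eff + s_eff
        profile <- config$task_profiles[[tk]]
        for (tr in seq_len(config$trials_per_task[[tk]])) {
          ev <- sample_trial(profile, config$trial_budget_ms, eff,
                             blink_prob = config$blink_prob,
                             long_fix_prob = config$long_fix_prob)
          ev$participant <- p_ids[pi]
          ev$session <- s_ids[si]
          ev$task <- tk
          ev$trial <- tr
          if (tk == "scene_search") {
            present <- stats::runif(1) < config$target_present_prob
            found <- present && stats::runif(1) < config$target_found_prob
            ev$target_present <- present
            ev$target_found <- found
          } else {
            ev$target_present <- NA
            ev$target_found <- NA
          }
          pieces[[length(pieces) + 1L]] <- ev
        }
      }
    }
  }
  out <- as.data.frame(data.table::rbindlist(pieces))
  out[, c("participant", "session", "task", "trial", "event_index",
          "event_type", "duration_ms", "amplitude_deg", "blink_before",
          "blink_after", "target_present", "target_found")]
}
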