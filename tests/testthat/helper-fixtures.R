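# Fixtures built in code: tiny event tables and feature matrices used
# across the test files.

# Minimal well-formed event table; durations/amplitudes chosen by hand.
make_events <- function(participant = "p01", session = "day1",
                        task = "reading", trial = 1,
                        fixdur = c(200, 250, 300),
                        saccamp = c(2, 4),
                        blink_before = NULL, blink_after = NULL,
                        target_present = NA, target_found = NA) {
  n <- length(fixdur) + length(saccamp)
  ev_type <- rep(c("fixation", "saccade"), length.out = n)
  df <- data.frame(
    participant = participant, session = session, task = task, trial = trial,
    event_index = seq_len(n) - 1L,
    event_type = ev_type,
    duration_ms = NA_real_, amplitude_deg = NA_real_,
    blink_before = FALSE, blink_after = FALSE,
    target_present = target_present, target_found = target_found,
    stringsAsFactors = FALSE)
  df$duration_ms[df$event_type == "fixation"] <- fixdur
  df$amplitude_deg[df$event_type == "saccade"] <- saccamp
  if (!is.null(blink_before)) df$blink_before[blink_before] <- TRUE
  if (!is.null(blink_after)) df$blink_after[blink_after] <- TRUE
  df
}

# Two well-separated Gaussian clusters per class in feature space.
make_separable <- function(n_per_class = 10, classes = c("a", "b"),
                           delta = 50, sd = 1, p = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(k)
    matrix(stats::rnorm(n_per_class * p, mean = k * delta, sd = sd),
           n_per_class, p)))
  list(x = x, y = rep(classes, each = n_per_class))
}

# Label-independent features: pure noise with balanced labels.
make_null_data <- function(n_per_class = 10, k = 4, p = 4, seed = 1) {
  set.seed(seed)
  n <- n_per_class * k
  list(x = matrix(stats::rnorm(n * p), n, p),
       y = rep(letters[seq_len(k)], each = n_per_class))
}

# Independent brute-force Gaussian naive Bayes log posteriors: explicit
# product of per-feature normal densities times the empirical prior,
# using ML (n-denominator) variances -- written with dnorm() only, no
# package internals.
brute_nb_log_posteriors <- function(train_x, train_y, test_x,
                                    variance_floor = 0) {
  classes <- sort(unique(train_y))
  t(apply(test_x, 1, function(xi) {
    vapply(classes, function(cl) {
      xc <- train_x[train_y == cl, , drop = FALSE]
      m <- colMeans(xc)
      v <- pmax(colMeans(xc^2) - m^2, variance_floor)
      log(nrow(xc) / nrow(train_x)) +
        sum(stats::dnorm(xi, mean = m, sd = sqrt(v), log = TRUE))
    }, numeric(1))
  }))
}

# Small cohort configuration for fast end-to-end tests.
small_cohort <- function(seed = 3, n_participants = 2) {
  cohort_config(
    n_participants = n_participants,
    trials_per_task = c(pseudo_reading = 8, reading = 8,
                        scene_memorization = 8, scene_search = 12),
    rng_seed = seed)
}
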