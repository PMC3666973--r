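# Trial-level feature representations. The four-feature summary is the
# mean and SD of fixation duration plus the mean and SD of saccade
# amplitude; the eight-feature summary appends the number of fixations and
# the three ex-Gaussian parameters fitted to the trial's fixation
# durations.

.feature_names <- function(mode) {
  four <- c("mean_fixdur", "sd_fixdur", "mean_saccamp", "sd_saccamp")
  if (mode == "four") four
  else c(four, "n_fixations", "exg_mu", "exg_sigma", "exg_tau")
}

#' Summarize one trial as a feature vector
#'
#' Computes the four- or eight-feature summary of a single trial from its
#' ordered fixation durations and saccade amplitudes. Standard deviations
#' use the n-1 denominator. In eight-feature mode an ex-Gaussian
#' distribution is fitted to the fixation durations, which requires at
#' least `min_n` fixations.
#'
#' @param fixdur Numeric vector of fixation durations (ms), length >= 2.
#' @param saccamp Numeric vector of saccade amplitudes (deg), length >= 2.
#' @param mode `"four"` or `"eight"`.
#' @param min_n Minimum fixations for the ex-Gaussian fit (default 8).
#' @param fit_method `"mle"` or `"quantile"` ex-Gaussian estimator.
#' @return Named numeric feature vector.
#' @export
extract_features <- function(fixdur, saccamp, mode = c("eight", "four"),
                             min_n = 8, fit_method = c("mle", "quantile")) {
  mode <- match.arg(mode)
  fit_method <- match.arg(fit_method)
  fixdur <- as.numeric(fixdur)
  saccamp <- as.numeric(saccamp)
  if (length(fixdur) < 2 || length(saccamp) < 2)
    stop("extract_features: need at least 2 fixations and 2 saccades",
         call. = FALSE)
  out <- c(mean_fixdur = mean(fixdur), sd_fixdur = stats::sd(fixdur),
           mean_saccamp = mean(saccamp), sd_saccamp = stats::sd(saccamp))
  if (mode == "four") return(out)
  if (length(fixdur) < min_n)
    stop(sprintf(paste0("extract_features: eight-feature mode needs >= %d ",
                        "fixations for the ex-Gaussian fit, got %d"),
                 min_n, length(fixdur)), call. = FALSE)
  fit <- switch(fit_method,
                mle = fit_exgauss_mle(fixdur, min_n = min_n),
                quantile = fit_exgauss_quantile(fixdur))
  c(out, n_fixations = length(fixdur),
    exg_mu = fit$mu, exg_sigma = fit$sigma, exg_tau = fit$tau)
}

#' Build the trial-by-feature matrix for an event table
#'
#' Applies [extract_features()] to every trial of a (preprocessed) event
#' table. Trials that do not meet the feature preconditions (too few
#' fixations or saccades) are dropped with a `message()`; the count is
#' attached as attribute `n_dropped_trials`.
#'
#' @param events Preprocessed event table.
#' @inheritParams extract_features
#' @return A data.frame with metadata columns (`participant`, `session`,
#'   `task`, `trial`) followed by the feature columns.
#' @export
feature_table <- function(events, mode = c("eight", "four"), min_n = 8,
                          fit_method = c("mle", "quantile")) {
  mode <- match.arg(mode)
  fit_method <- match.arg(fit_method)
  key <- interaction(events$participant, events$session, events$task,
                     events$trial, drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(events)), key)
  rows <- vector("list", length(idx))
  dropped <- 0L
  for (i in seq_along(idx)) {
    rs <- idx[[i]]
    sub <- events[rs, ]
    fixdur <- sub$duration_ms[sub$event_type == "fixation"]
    saccamp <- sub$amplitude_deg[sub$event_type == "saccade"]
    need <- if (mode == "eight") max(2, min_n) else 2
    if (length(fixdur) < need || length(saccamp) < 2) {
      dropped <- dropped + 1L
      next
    }
    fv <- extract_features(fixdur, saccamp, mode = mode, min_n = min_n,
                           fit_method = fit_method)
    rows[[i]] <- data.frame(
      participant = sub$participant[1], session = sub$session[1],
      task = sub$task[1], trial = sub$trial[1],
      as.list(fv), stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    message(sprintf("feature_table: dropped %d trial(s) below the %s",
                    dropped, "feature preconditions"))
  out <- as.data.frame(data.table::rbindlist(rows[!vapply(rows, is.null,
                                                          logical(1))]))
  out <- out[order(out$participant, out$session, out$task, out$trial), ]
  rownames(out) <- NULL
  attr(out, "n_dropped_trials") <- dropped
  attr(out, "mode") <- mode
  out
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param ft Result of [feature_table()].
#' @return Numeric matrix, one row per trial.
#' @export
feature_matrix <- function(ft) {
  cols <- setdiff(names(ft), c("participant", "session", "task", "trial"))
  as.matrix(ft[cols])
}
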