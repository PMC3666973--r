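# End-to-end experiment runner: preprocessing -> features -> per-participant
# classification -> optional permutation tests, over the factorial of
# designs (four-task vs the two scene tasks), feature modes (four vs
# eight) and evaluation schemes (within-session leave-one-out vs
# cross-session).

#' Experiment configuration
#'
#' @param cohort A [cohort_config()] to simulate from, or a path to an
#'   event-table CSV in the dialect of [read_event_table()].
#' @param designs Subset of `c("four_task", "scene_two_task")`.
#' @param feature_modes Subset of `c("four", "eight")`.
#' @param schemes Subset of `c("within_loocv", "cross_session")`.
#' @param n_perm Permutations per classification model (0 disables the
#'   permutation tests).
#' @param alpha Significance level for the permutation tests.
#' @param seed Integer seed for the permutation streams.
#' @param fit_method Ex-Gaussian estimator for eight-feature mode.
#' @param out_dir Optional directory: when given, accuracies, per-cell
#'   summaries and confusion matrices are written there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              designs = c("four_task", "scene_two_task"),
                              feature_modes = c("four", "eight"),
                              schemes = c("within_loocv", "cross_session"),
                              n_perm = 0, alpha = 0.05, seed = 1L,
                              fit_method = c("mle", "quantile"),
                              out_dir = NULL) {
  designs <- match.arg(designs, several.ok = TRUE)
  feature_modes <- match.arg(feature_modes, several.ok = TRUE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  fit_method <- match.arg(fit_method)
  if (length(designs) < 1 || length(feature_modes) < 1 || length(schemes) < 1)
    stop("experiment_config: select at least one design, mode and scheme",
         call. = FALSE)
  structure(list(cohort = cohort, designs = designs,
                 feature_modes = feature_modes, schemes = schemes,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 fit_method = fit_method, out_dir = out_dir),
            class = "experiment_config")
}

.design_tasks <- function(design) {
  switch(design,
         four_task = gaze_tasks(),
         scene_two_task = c("scene_memorization", "scene_search"),
         stop("unknown design: ", design, call. = FALSE))
}

#' Run the full decoding experiment
#'
#' For every participant and every selected design x feature-mode x
#' scheme cell: within-session cells run leave-one-out cross-validation
#' separately per session; cross-session cells train on each session and
#' test on the other (both directions). Classifiers are always fit per
#' participant -- there is no pooled cross-participant model. Stage errors
#' in one cell are logged and do not stop the remaining cells.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result` with elements
#'   `accuracies` (one row per participant x cell x session/direction,
#'   with p-values when permutation tests were run), `summary` (mean/SD
#'   of accuracy across participants per cell, and the number of
#'   significant participants when tested), and `confusions` (named list
#'   of row-normalized confusion matrices).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  events <- if (is.character(config$cohort)) read_event_table(config$cohort)
  else generate_cohort(config$cohort)
  events <- preprocess_events(events)
  feats <- list()
  for (mode in config$feature_modes)
    feats[[mode]] <- feature_table(events, mode = mode,
                                   fit_method = config$fit_method)
  participants <- sort(unique(events$participant))
  sessions <- sort(unique(events$session))
  rows <- list()
  confusions <- list()
  perm_seed <- config$seed
  for (p in participants) {
    for (design in config$designs) {
      tasks <- .design_tasks(design)
      for (mode in config$feature_modes) {
        ft <- feats[[mode]]
        ft_p <- ft[ft$participant == p & ft$task %in% tasks, ]
        for (scheme in config$schemes) {
          cell <- sprintf("%s_%s_%s", design, mode, scheme)
          res <- tryCatch(
            .run_cell(ft_p, scheme, sessions, tasks, config, perm_seed),
            error = function(e) {
              message(sprintf("run_experiment: %s / %s failed: %s",
                              p, cell, conditionMessage(e)))
              NULL
            })
          perm_seed <- perm_seed + 1L
          if (is.null(res)) next
          for (r in res) {
            rows[[length(rows) + 1L]] <- data.frame(
              participant = p, design = design, mode = mode,
              scheme = scheme, unit = r$unit, accuracy = r$accuracy,
              n_trials = r$n, p_value = r$p_value,
              stringsAsFactors = FALSE)
            confusions[[paste(p, cell, r$unit, sep = "_")]] <- r$confusion
          }
        }
      }
    }
  }
  accuracies <- as.data.frame(data.table::rbindlist(rows))
  agg <- stats::aggregate(accuracy ~ design + mode + scheme, accuracies,
                          function(a) c(mean = mean(a), sd = stats::sd(a)))
  summary_df <- data.frame(agg[c("design", "mode", "scheme")],
                           mean_accuracy = agg$accuracy[, "mean"],
                           sd_accuracy = agg$accuracy[, "sd"])
  if (config$n_perm > 0) {
    sig <- stats::aggregate(
      p_value ~ design + mode + scheme + participant, accuracies,
      function(p) all(p <= config$alpha))
    nsig <- stats::aggregate(p_value ~ design + mode + scheme, sig, sum)
    names(nsig)[names(nsig) == "p_value"] <- "n_significant"
    summary_df <- merge(summary_df, nsig,
                        by = c("design", "mode", "scheme"))
  }
  out <- structure(list(accuracies = accuracies, summary = summary_df,
                        confusions = confusions, config = config),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) .write_experiment(out, config$out_dir)
  out
}

# one participant x design x mode x scheme cell; returns a list of result
# records (one per session for within, one per direction for cross)
.run_cell <- function(ft_p, scheme, sessions, tasks, config, perm_seed) {
  class_order <- tasks
  out <- list()
  if (scheme == "within_loocv") {
    for (s in sessions) {
      sub <- ft_p[ft_p$session == s, ]
      x <- feature_matrix(sub)
      cv <- loocv(x, sub$task, class_order = class_order)
      p_value <- NA_real_
      if (config$n_perm > 0) {
        pr <- permutation_null(x, sub$task, scheme = "loocv",
                               n_perm = config$n_perm, alpha = config$alpha,
                               seed = perm_seed, class_order = class_order)
        p_value <- pr$p_value
      }
      out[[length(out) + 1L]] <- list(unit = s, accuracy = cv$accuracy,
                                      n = cv$n, confusion = cv$confusion,
                                      p_value = p_value)
    }
  } else {
    if (length(sessions) < 2)
      stop("cross_session scheme needs at least 2 sessions", call. = FALSE)
    dirs <- list(c(1L, 2L), c(2L, 1L))
    for (d in dirs) {
      tr <- ft_p[ft_p$session == sessions[d[1]], ]
      te <- ft_p[ft_p$session == sessions[d[2]], ]
      cv <- cross_session(feature_matrix(tr), tr$task,
                          feature_matrix(te), te$task,
                          class_order = class_order)
      p_value <- NA_real_
      if (config$n_perm > 0) {
        pr <- permutation_null(feature_matrix(tr), tr$task,
                               scheme = "cross_session",
                               test_x = feature_matrix(te), test_y = te$task,
                               n_perm = config$n_perm, alpha = config$alpha,
                               seed = perm_seed, class_order = class_order)
        p_value <- pr$p_value
      }
      out[[length(out) + 1L]] <- list(
        unit = sprintf("%s_to_%s", sessions[d[1]], sessions[d[2]]),
        accuracy = cv$accuracy, n = cv$n, confusion = cv$confusion,
        p_value = p_value)
    }
  }
  out
}

.write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$accuracies,
                   file.path(out_dir, "accuracies.csv"), row.names = FALSE)
  utils::write.csv(result$summary,
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (nm in names(result$confusions)) {
    utils::write.csv(as.data.frame(result$confusions[[nm]]),
                     file.path(out_dir, sprintf("confusion_%s.csv", nm)))
  }
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("decoding experiment over", length(unique(x$accuracies$participant)),
      "participants\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
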