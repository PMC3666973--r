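# Permutation-based significance of classification accuracy: the observed
# accuracy is compared against an empirical null distribution formed by
# re-running the full classification scheme after randomly permuting the
# training labels. The test labels are never permuted, so each null
# accuracy is scored against the truth.

#' Empirical permutation null for classification accuracy
#'
#' Re-runs the chosen classification scheme `n_perm` times with uniformly
#' permuted training labels and records the resulting accuracies. Under
#' leave-one-out cross-validation one permutation of the full label vector
#' is drawn per iteration and, within each fold, the training portion of
#' that permuted vector is used, so each iteration is internally
#' consistent; under cross-session evaluation only the training-set labels
#' are permuted. The p-value uses the permutation-inclusive estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never exactly
#' zero and ties count against rejection.
#'
#' @param x Feature matrix (training set for `"cross_session"`).
#' @param y Labels for `x`.
#' @param scheme `"loocv"` or `"cross_session"`.
#' @param test_x,test_y Test set, required for `"cross_session"`.
#' @param n_perm Number of permutations (default 2000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed for the permutation stream.
#' @param class_order Optional explicit class order.
#' @return An object of class `permutation_result` with the observed
#'   accuracy, the vector of null accuracies, the p-value and the
#'   rejection flag at `alpha`.
#' @export
permutation_null <- function(x, y, scheme = c("loocv", "cross_session"),
                             test_x = NULL, test_y = NULL, n_perm = 2000,
                             alpha = 0.05, seed = NULL, class_order = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("permutation_null: n_perm must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("permutation_null: alpha must lie in (0, 1)", call. = FALSE)
  x <- as.matrix(x)
  y <- as.character(y)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  if (scheme == "loocv") {
    if (is.null(class_order)) class_order <- sort(unique(y))
    vf <- .variance_floor(x)
    observed <- mean(class_order[.loocv_core(x, y, vf, class_order)] == y)
    null_acc <- vapply(seq_len(n_perm), function(b) {
      perm <- sample(y)
      mean(class_order[.loocv_core(x, perm, vf, class_order)] == y)
    }, numeric(1))
  } else {
    if (is.null(test_x) || is.null(test_y))
      stop("permutation_null: cross_session needs test_x and test_y",
           call. = FALSE)
    test_y <- as.character(test_y)
    if (is.null(class_order)) class_order <- sort(unique(c(y, test_y)))
    observed <- cross_session(x, y, test_x, test_y,
                              class_order = class_order)$accuracy
    null_acc <- vapply(seq_len(n_perm), function(b) {
      cross_session(x, sample(y), test_x, test_y,
                    class_order = class_order)$accuracy
    }, numeric(1))
  }
  p_value <- (1 + sum(null_acc >= observed)) / (1 + n_perm)
  structure(list(observed_accuracy = observed, null_accuracies = null_acc,
                 p_value = p_value, n_perm = n_perm, alpha = alpha,
                 reject = p_value <= alpha, scheme = scheme),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation test (%s): observed accuracy %.3f, ",
                     "null mean %.3f (%d permutations)\n"),
              x$scheme, x$observed_accuracy, mean(x$null_accuracies),
              x$n_perm))
  cat(sprintf("  p = %.4g; %s at alpha = %.3g\n", x$p_value,
              if (x$reject) "reject" else "fail to reject", x$alpha))
  invisible(x)
}

#' Decide significance of a permutation test result
#'
#' @param result A [permutation_null()] result.
#' @param alpha Significance level in (0, 1); defaults to the level stored
#'   in `result`.
#' @return A list with `p_value`, `alpha`, `reject` and a one-line
#'   human-readable `summary`.
#' @export
evaluate_significance <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "permutation_result"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("evaluate_significance: alpha must lie in (0, 1)", call. = FALSE)
  reject <- result$p_value <= alpha
  summary <- sprintf(
    "observed accuracy %.3f vs null mean %.3f: p = %.4g, %s at alpha = %.3g",
    result$observed_accuracy, mean(result$null_accuracies), result$p_value,
    if (reject) "significant" else "not significant", alpha)
  list(p_value = result$p_value, alpha = alpha, reject = reject,
       summary = summary)
}
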