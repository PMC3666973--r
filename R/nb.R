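# Gaussian Naive Bayes, written from scratch: per-class empirical priors
# and independent per-feature Gaussian likelihoods with maximum-likelihood
# (n-denominator) variances, floored at a small fraction of the global
# feature variance to protect degenerate folds. Evaluation schemes:
# within-session leave-one-out cross-validation (computed with O(1)
# per-fold downdating of the class sufficient statistics) and
# cross-session train/test.

.as_label_factor <- function(y, class_order = NULL) {
  if (is.null(class_order)) factor(y) else {
    if (!all(y %in% class_order))
      stop("unknown label(s): ",
           paste(unique(setdiff(y, class_order)), collapse = ", "),
           call. = FALSE)
    factor(y, levels = class_order)
  }
}

# Per-feature variance floor: a small relative fraction of the pooled
# (global) ML variance, with an absolute fallback for constant features.
.variance_floor <- function(x, rel = 1e-9) {
  n <- nrow(x)
  g_mean <- colMeans(x)
  g_var <- colMeans(x^2) - g_mean^2
  pmax(rel * g_var, 1e-12)
}

#' Fit a Gaussian Naive Bayes model
#'
#' Estimates per-class priors (empirical class frequencies, or uniform)
#' and, independently for every feature, a per-class Gaussian likelihood
#' with the maximum-likelihood variance (n denominator). Variances are
#' floored at `floor_rel` times the global per-feature variance so that a
#' degenerate class cannot produce an infinite density.
#'
#' @param x Numeric matrix, one row per trial.
#' @param y Class labels (coerced to factor; factor level order is the
#'   tie-breaking and confusion-matrix order).
#' @param floor_rel Relative variance floor (default 1e-9).
#' @param variance_floor Optional explicit per-feature floor vector,
#'   overriding `floor_rel` (used internally to keep cross-validation
#'   folds comparable).
#' @param priors `"empirical"` (default) or `"uniform"`.
#' @return An object of class `gaussian_nb` with elements `class_labels`,
#'   `log_priors`, `means` (class x feature), `variances`.
#' @export
fit_nb <- function(x, y, floor_rel = 1e-9, variance_floor = NULL,
                   priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  y <- .as_label_factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("fit_nb: need at least 2 classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2))
    stop("fit_nb: class(es) with fewer than 2 trials: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  s <- rowsum(x, y)
  q <- rowsum(x^2, y)
  nc <- as.numeric(counts)
  means <- s / nc
  vars <- q / nc - means^2
  if (is.null(variance_floor)) variance_floor <- .variance_floor(x, floor_rel)
  vars <- sweep(vars, 2, variance_floor, pmax)
  log_priors <- if (priors == "empirical") log(nc / sum(nc))
  else rep(-log(nlevels(y)), nlevels(y))
  structure(list(class_labels = levels(y),
                 log_priors = stats::setNames(log_priors, levels(y)),
                 means = means, variances = vars),
            class = "gaussian_nb")
}

#' @export
print.gaussian_nb <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes model: %d classes, %d features\n",
              length(x$class_labels), ncol(x$means)))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

# class-wise log posteriors (up to the shared evidence constant) for a
# matrix of observations; K x p model parameters, n x p data -> n x K.
.nb_log_posteriors <- function(log_priors, means, vars, x) {
  n <- nrow(x); K <- nrow(means)
  lp <- matrix(NA_real_, n, K, dimnames = list(NULL, rownames(means)))
  const <- -0.5 * rowSums(log(2 * pi * vars))
  for (k in seq_len(K)) {
    d <- sweep(x, 2, means[k, ])
    lp[, k] <- log_priors[k] + const[k] -
      0.5 * rowSums(sweep(d^2, 2, vars[k, ], `/`))
  }
  lp
}

#' Predict with a Gaussian Naive Bayes model
#'
#' Computes, for every row of `x`, the per-class log posterior (log prior
#' plus the sum of per-feature Gaussian log densities) and returns the
#' argmax label. Exact ties are broken deterministically in favour of the
#' class that comes first in the model's class order.
#'
#' @param model A [fit_nb()] result.
#' @param x Numeric matrix (or single vector) with the model's feature
#'   count.
#' @return List with `labels` (character vector) and `log_posteriors`
#'   (n x K matrix, unnormalized).
#' @export
predict_nb <- function(model, x) {
  stopifnot(inherits(model, "gaussian_nb"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop(sprintf("predict_nb: model has %d features, x has %d",
                 ncol(model$means), ncol(x)), call. = FALSE)
  lp <- .nb_log_posteriors(model$log_priors, model$means, model$variances, x)
  labels <- model$class_labels[max.col(lp, ties.method = "first")]
  list(labels = labels, log_posteriors = lp)
}

#' Row-normalized confusion matrix
#'
#' Entry (i, j) is the proportion of trials with true class i that were
#' predicted as class j; a perfect classifier gives the identity matrix.
#' Classes absent from `true_labels` yield an all-zero row, recorded in
#' attribute `empty_classes`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_order Class order for rows/columns (default: sorted union).
#' @return K x K numeric matrix.
#' @export
confusion <- function(true_labels, predicted_labels, class_order = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("confusion: label vectors must have equal length", call. = FALSE)
  if (is.null(class_order))
    class_order <- sort(unique(c(true_labels, predicted_labels)))
  tf <- .as_label_factor(true_labels, class_order)
  pf <- .as_label_factor(predicted_labels, class_order)
  counts <- table(true = tf, predicted = pf)
  n_true <- rowSums(counts)
  cm <- unclass(counts) / ifelse(n_true > 0, n_true, 1)
  cm <- matrix(as.numeric(cm), nrow(counts), ncol(counts),
               dimnames = dimnames(counts))
  if (any(n_true == 0))
    attr(cm, "empty_classes") <- class_order[n_true == 0]
  cm
}

.cv_result <- function(true, predicted, class_order) {
  acc <- mean(predicted == true)
  structure(list(true = true, predicted = predicted, accuracy = acc,
                 confusion = confusion(true, predicted, class_order),
                 n = length(true)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("classification result: accuracy %.3f over %d trials\n",
              x$accuracy, x$n))
  invisible(x)
}

# Core leave-one-out engine: returns the integer index (into class_order)
# of the predicted class for every fold. `train_y` are the labels the
# classifier is trained on; under label permutation these are shuffled
# while accuracy is still judged against the true labels by the caller.
# Per-fold models are obtained by downdating the class sums / sums of
# squares, which is algebraically identical to refitting on the n-1
# remaining rows with the same (full-data) variance floor.
.loocv_core <- function(x, train_y, variance_floor, class_order) {
  n <- nrow(x); K <- length(class_order)
  yf <- factor(train_y, levels = class_order)
  yi <- as.integer(yf)
  counts <- tabulate(yi, nbins = K)
  if (any(counts < 2))
    stop("loocv: class(es) with fewer than 2 training trials", call. = FALSE)
  s <- rowsum(x, yf)
  q <- rowsum(x^2, yf)
  base_means <- s / counts
  base_vars <- q / counts - base_means^2
  pred <- integer(n)
  log2pi <- log(2 * pi)
  for (i in seq_len(n)) {
    ci <- yi[i]
    xi <- x[i, ]
    nc <- counts
    nc[ci] <- nc[ci] - 1L
    means <- base_means
    vars <- base_vars
    m_ci <- (s[ci, ] - xi) / nc[ci]
    means[ci, ] <- m_ci
    vars[ci, ] <- (q[ci, ] - xi^2) / nc[ci] - m_ci^2
    vars <- sweep(vars, 2, variance_floor, pmax)
    lp <- log(nc / (n - 1)) - 0.5 * rowSums(log2pi + log(vars)) -
      0.5 * rowSums(sweep(means, 2, xi)^2 / vars)
    pred[i] <- which.max(lp)
  }
  pred
}

#' Leave-one-out cross-validated Naive Bayes classification
#'
#' For each trial, a Gaussian Naive Bayes model is trained on all other
#' trials and used to predict the held-out trial; accuracy is the
#' proportion of correct predictions over all n folds. The per-feature
#' variance floor is computed once from the full feature matrix so every
#' fold uses the same floor.
#'
#' @param x Numeric feature matrix.
#' @param y Labels; every class must have at least 3 trials.
#' @param class_order Optional explicit class order (tie-breaking).
#' @param floor_rel Relative variance floor (default 1e-9).
#' @return A `cv_result`: per-trial true/predicted labels, `accuracy`, and
#'   a row-normalized `confusion` matrix.
#' @export
loocv <- function(x, y, class_order = NULL, floor_rel = 1e-9) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("loocv: x and y disagree", call. = FALSE)
  if (nrow(x) < 3) stop("loocv: need n >= 3", call. = FALSE)
  counts <- table(y)
  if (any(counts < 3))
    stop("loocv: class(es) with fewer than 3 trials: ",
         paste(names(counts)[counts < 3], collapse = ", "), call. = FALSE)
  if (is.null(class_order)) class_order <- sort(unique(y))
  vf <- .variance_floor(x, floor_rel)
  pred <- .loocv_core(x, y, vf, class_order)
  .cv_result(y, class_order[pred], class_order)
}

#' Cross-session Naive Bayes classification
#'
#' Fits a single model on the training set and evaluates it on every test
#' trial (no pooling of sessions: callers pass one session as training
#' data and the other as test data, in each direction).
#'
#' @param train_x,train_y Training feature matrix and labels.
#' @param test_x,test_y Test feature matrix and labels.
#' @param class_order Optional explicit class order.
#' @param floor_rel Relative variance floor.
#' @return A `cv_result`.
#' @export
cross_session <- function(train_x, train_y, test_x, test_y,
                          class_order = NULL, floor_rel = 1e-9) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x))
    stop("cross_session: feature dimensionality mismatch", call. = FALSE)
  train_y <- as.character(train_y); test_y <- as.character(test_y)
  if (is.null(class_order))
    class_order <- sort(unique(c(train_y, test_y)))
  model <- fit_nb(train_x, factor(train_y, levels = class_order),
                  floor_rel = floor_rel)
  pred <- predict_nb(model, test_x)$labels
  .cv_result(test_y, pred, class_order)
}
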