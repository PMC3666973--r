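# Gaussian naive Bayes: fitting, prediction, cross-validation schemes and
# the confusion matrix.

test_that("fit_nb matches hand-computed parameters on a degenerate case", {
  x <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  m <- fit_nb(x, y)
  expect_equal(unname(m$means[, 1]), c(0, 1))
  expect_equal(unname(exp(m$log_priors)), c(0.5, 0.5))
  # zero within-class variance is caught by the floor
  expect_true(all(m$variances > 0))
  expect_equal(unname(m$variances[, 1]),
               pmax(1e-9 * 0.25, 1e-12) * c(1, 1))  # global ML var = 0.25
})

test_that("priors equal training class proportions", {
  set.seed(40)
  counts <- c(pseudo_reading = 35, reading = 35, scene_memorization = 40,
              scene_search = 48)
  y <- rep(names(counts), counts)
  x <- matrix(stats::rnorm(length(y) * 3), ncol = 3)
  m <- fit_nb(x, y)
  expect_equal(exp(m$log_priors), counts / sum(counts),
               ignore_attr = TRUE)
  m_u <- fit_nb(x, y, priors = "uniform")
  expect_equal(unname(exp(m_u$log_priors)), rep(0.25, 4))
})

test_that("fit_nb agrees with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(41)
  x <- matrix(stats::rnorm(50 * 8, sd = 2), 50, 8)
  y <- sample(rep(c("a", "b", "c"), c(20, 15, 15)))
  ours <- fit_nb(x, y)
  ref <- e1071::naiveBayes(x, factor(y))
  for (k in seq_along(ours$class_labels)) {
    nc <- sum(y == ours$class_labels[k])
    ref_tab <- t(vapply(ref$tables, function(tb) tb[k, ], numeric(2)))
    expect_equal(unname(ours$means[k, ]), unname(ref_tab[, 1]),
                 tolerance = 1e-10)
    # e1071 stores n-1 denominator SDs; ours are ML variances
    expect_equal(unname(ours$variances[k, ]),
                 unname(ref_tab[, 2]^2 * (nc - 1) / nc), tolerance = 1e-10)
  }
  expect_equal(exp(ours$log_priors), ref$apriori / sum(ref$apriori),
               ignore_attr = TRUE)
})

test_that("posteriors equal a brute-force Bayes computation", {
  set.seed(42)
  x <- matrix(stats::rnorm(60 * 4, mean = rep(c(0, 1, 3), each = 20)), 60, 4)
  y <- rep(c("a", "b", "c"), each = 20)
  xt <- matrix(stats::rnorm(10 * 4), 10, 4)
  m <- fit_nb(x, y)
  lp <- predict_nb(m, xt)$log_posteriors
  oracle <- brute_nb_log_posteriors(x, y, xt,
                                    variance_floor = 1e-9 *
                                      (colMeans(x^2) - colMeans(x)^2))
  # same up to the shared evidence constant: compare normalized posteriors
  norm <- function(l) l - apply(l, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  expect_equal(norm(lp), norm(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("exact ties break to the first class in model order", {
  x <- matrix(c(-2, -1, 0, 0, 1, 2), ncol = 1)
  y <- rep(c("first", "second"), each = 3)
  m <- fit_nb(x, y)  # symmetric classes around 0... means -1 and 1
  p <- predict_nb(m, matrix(0))
  expect_equal(p$labels, "first")
  expect_equal(unname(p$log_posteriors[1, "first"]),
               unname(p$log_posteriors[1, "second"]))
  # off the tie point the nearer class wins
  expect_equal(predict_nb(m, matrix(1))$labels, "second")
})

test_that("training and prediction validate their inputs", {
  x <- matrix(stats::rnorm(10), 5, 2)
  expect_error(fit_nb(x, c("a", "a", "a", "a", "b")), "fewer than 2")
  expect_error(fit_nb(x, rep("a", 5)), "2 classes")
  m <- fit_nb(matrix(stats::rnorm(20), 10, 2), rep(c("a", "b"), 5))
  expect_error(predict_nb(m, matrix(0, 1, 3)), "features")
})

test_that("loocv is perfect on separable clusters and chance on noise", {
  sep <- make_separable(n_per_class = 8, classes = c("a", "b", "c", "d"),
                        delta = 50, sd = 1, seed = 43)
  expect_equal(loocv(sep$x, sep$y)$accuracy, 1.0)
  # labels independent of features: accuracy near 1/4
  nul <- make_null_data(n_per_class = 50, k = 4, p = 4, seed = 44)
  acc <- loocv(nul$x, nul$y)$accuracy
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / length(nul$y)) + 0.02)
})

test_that("every loocv fold equals an explicit refit on the rest", {
  set.seed(45)
  n <- 24
  x <- matrix(stats::rnorm(n * 3, mean = rep(c(0, 1.5, 3), each = n / 3)),
              n, 3)
  y <- rep(c("a", "b", "c"), each = n / 3)
  res <- loocv(x, y)
  vf <- pmax(1e-9 * (colMeans(x^2) - colMeans(x)^2), 1e-12)
  manual <- vapply(seq_len(n), function(i) {
    m <- fit_nb(x[-i, ], y[-i], variance_floor = vf)
    predict_nb(m, x[i, , drop = FALSE])$labels
  }, character(1))
  expect_equal(res$predicted, manual)
  expect_equal(res$accuracy, mean(manual == y))
})

test_that("loocv enforces its class-size precondition", {
  x <- matrix(stats::rnorm(10), 5, 2)
  expect_error(loocv(x, c("a", "a", "a", "b", "b")), "b")
})

test_that("per-feature rescaling leaves predictions unchanged", {
  set.seed(46)
  x <- matrix(stats::rnorm(40 * 4, mean = rep(c(0, 2), each = 20)), 40, 4)
  y <- rep(c("a", "b"), each = 20)
  x2 <- x
  x2[, 3] <- x2[, 3] * 1000
  expect_equal(loocv(x, y)$predicted, loocv(x2, y)$predicted)
})

test_that("label relabelling permutes outputs consistently", {
  set.seed(47)
  x <- matrix(stats::rnorm(30 * 2, mean = rep(c(0, 1, 4), each = 10)), 30, 2)
  y <- rep(c("a", "b", "c"), each = 10)
  map <- c(a = "z", b = "y", c = "x")
  res1 <- loocv(x, y)
  res2 <- loocv(x, unname(map[y]))
  expect_equal(res2$accuracy, res1$accuracy)
  expect_equal(res2$predicted, unname(map[res1$predicted]))
})

test_that("cross-session evaluation reduces to direct fit and predict", {
  sep <- make_separable(n_per_class = 6, classes = c("a", "b"), delta = 30,
                        seed = 48)
  # test identical to train: perfect
  expect_equal(cross_session(sep$x, sep$y, sep$x, sep$y)$accuracy, 1.0)
  # worked instance: 6 train / 4 test, checked against explicit Bayes
  set.seed(49)
  tr_x <- matrix(c(1, 1.2, 0.8, 5, 5.3, 4.7), ncol = 1)
  tr_y <- rep(c("low", "high"), each = 3)
  te_x <- matrix(c(0.9, 2.9, 3.2, 5.1), ncol = 1)
  te_y <- c("low", "low", "high", "high")
  res <- cross_session(tr_x, tr_y, te_x, te_y)
  oracle_lp <- brute_nb_log_posteriors(tr_x, tr_y, te_x)
  oracle_pred <- colnames(oracle_lp)[max.col(oracle_lp)]
  expect_equal(res$predicted, oracle_pred)
  expect_equal(res$accuracy, mean(oracle_pred == te_y))
  # label-independent test features: accuracy near the max class prior
  set.seed(50)
  big_tr <- make_separable(n_per_class = 100, classes = c("a", "b"),
                           delta = 0.01, sd = 1, seed = 50)
  te <- matrix(stats::rnorm(400), 200, 2)
  acc <- cross_session(big_tr$x, big_tr$y, te,
                       sample(c("a", "b"), 200, TRUE))$accuracy
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("confusion matrix is row-normalized with documented edge cases", {
  true <- c("a", "a", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "a")
  cm <- confusion(true, pred)
  expect_equal(rowSums(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["a", "b"], 0.5)
  # perfect prediction: identity
  expect_equal(confusion(true, true), diag(3), ignore_attr = TRUE)
  # everything predicted as one class: that column is all ones
  expect_equal(unname(confusion(true, rep("b", 5))[, "b"]), rep(1, 3))
  # class order argument controls rows; absent classes yield zero rows
  cm2 <- confusion(c("a", "a"), c("a", "a"),
                   class_order = c("b", "a"))
  expect_equal(attr(cm2, "empty_classes"), "b")
  expect_equal(unname(cm2["b", ]), c(0, 0))
  expect_error(confusion("a", "q", class_order = "a"), "unknown label")
  expect_error(confusion(c("a", "b"), "a"), "equal length")
})

test_that("accuracy equals the prior-weighted confusion diagonal", {
  nul <- make_null_data(n_per_class = 20, k = 3, p = 3, seed = 51)
  res <- loocv(nul$x, nul$y)
  p_true <- table(res$true) / length(res$true)
  expect_equal(res$accuracy,
               sum(p_true * diag(res$confusion)), ignore_attr = TRUE)
})
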