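#' Ex-Gaussian parameter set
#'
#' Bundles the three parameters of an ex-Gaussian distribution, the
#' convolution of a Normal(mu, sigma) and an Exponential with mean tau.
#' Fixation durations in many eye-movement tasks are well described by this
#' family: mu and sigma capture the location and spread of the central bulk,
#' tau the heaviness of the right tail. The distribution mean is `mu + tau`
#' and the variance `sigma^2 + tau^2`.
#'
#' @param mu Gaussian component mean (ms).
#' @param sigma Gaussian component standard deviation (ms), strictly positive.
#' @param tau Exponential component mean (ms), strictly positive.
#' @return An object of class `exgauss_params`.
#' @examples
#' exgauss_params(250, 50, 150)
#' @export
exgauss_params <- function(mu, sigma, tau) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            length(mu) == 1L, length(sigma) == 1L, length(tau) == 1L,
            is.finite(mu), is.finite(sigma), is.finite(tau))
  if (sigma <= 0) stop("exgauss_params: sigma must be > 0", call. = FALSE)
  if (tau <= 0) stop("exgauss_params: tau must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}

#' @export
print.exgauss_params <- function(x, ...) {
  cat(sprintf("ex-Gaussian parameters: mu = %.3f, sigma = %.3f, tau = %.3f\n",
              x$mu, x$sigma, x$tau))
  cat(sprintf("  mean = %.3f, sd = %.3f\n",
              x$mu + x$tau, sqrt(x$sigma^2 + x$tau^2)))
  invisible(x)
}

# When tau is tiny relative to sigma the analytic density suffers
# catastrophic cancellation (exp(sigma^2/2tau^2) against log Phi); below
# this ratio the distribution is numerically Gaussian.
.exg_tau_ratio_floor <- 0.05

#' Ex-Gaussian density
#'
#' Density of the ex-Gaussian distribution, evaluated in a numerically
#' stable form: the Gaussian cdf enters through `pnorm(..., log.p = TRUE)`
#' so extreme arguments do not underflow. For `tau < 0.05 * sigma` the
#' density degenerates to the Normal density.
#'
#' @param x Quantiles (ms).
#' @param mu,sigma,tau Distribution parameters; see [exgauss_params()].
#' @param log If `TRUE`, return log density.
#' @return Numeric vector of (log) densities.
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  if (sigma <= 0 || tau <= 0)
    stop("dexgauss: sigma and tau must be > 0", call. = FALSE)
  if (tau < .exg_tau_ratio_floor * sigma) {
    lf <- stats::dnorm(x, mean = mu, sd = sigma, log = TRUE)
  } else {
    z <- (x - mu) / sigma - sigma / tau
    lf <- -log(tau) - (x - mu) / tau + sigma^2 / (2 * tau^2) +
      stats::pnorm(z, log.p = TRUE)
  }
  if (log) lf else exp(lf)
}

#' Ex-Gaussian cumulative distribution function
#'
#' @inheritParams dexgauss
#' @param q Quantiles (ms).
#' @return Numeric vector of probabilities.
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  if (sigma <= 0 || tau <= 0)
    stop("pexgauss: sigma and tau must be > 0", call. = FALSE)
  if (tau < .exg_tau_ratio_floor * sigma)
    return(stats::pnorm(q, mean = mu, sd = sigma))
  u <- (q - mu) / sigma
  z <- u - sigma / tau
  tail <- exp(sigma^2 / (2 * tau^2) - (q - mu) / tau +
                stats::pnorm(z, log.p = TRUE))
  pmin(pmax(stats::pnorm(u) - tail, 0), 1)
}

#' Draw ex-Gaussian variates
#'
#' Each draw is the sum of an independent Normal(mu, sigma) and an
#' Exponential variate with mean tau. Reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param mu,sigma,tau Distribution parameters, or pass an
#'   [exgauss_params()] object as `mu`.
#' @return Numeric vector of length `n` (ms).
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  if (inherits(mu, "exgauss_params")) {
    p <- mu; mu <- p$mu; sigma <- p$sigma; tau <- p$tau
  }
  if (sigma <= 0 || tau <= 0)
    stop("rexgauss: sigma and tau must be > 0", call. = FALSE)
  if (n < 1) stop("rexgauss: n must be >= 1", call. = FALSE)
  stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1 / tau)
}

# Moment-based starting point for the ex-Gaussian optimizers: tau0 from the
# sample skewness, clamped away from 0 and from the full sample SD.
.exg_init <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- max(abs(m) * 0.1, 1)
  skew <- mean((x - m)^3) / s^3
  tau0 <- s * (max(skew, 0.01) / 2)^(1 / 3)
  tau0 <- min(max(tau0, 0.05 * s), 0.95 * s)
  mu0 <- m - tau0
  sigma0 <- sqrt(max(s^2 - tau0^2, (0.1 * s)^2))
  c(mu = mu0, sigma = sigma0, tau = tau0)
}

.exg_fit_result <- function(par, loglik, converged, method, n) {
  out <- exgauss_params(par[[1]], par[[2]], par[[3]])
  attr(out, "loglik") <- loglik
  attr(out, "converged") <- converged
  attr(out, "method") <- method
  attr(out, "n") <- n
  out
}

#' Fit an ex-Gaussian distribution by maximum likelihood
#'
#' Maximizes the ex-Gaussian log-likelihood with bounded quasi-Newton
#' optimization (L-BFGS-B) from a moment-based start. sigma and tau are
#' bounded below by 1e-3 ms so the fit cannot collapse onto the boundary
#' of the parameter space. The returned log-likelihood is never worse than
#' the log-likelihood at the starting point.
#'
#' @param x Observed durations (ms); all finite.
#' @param min_n Minimum number of observations required (default 8).
#' @return An [exgauss_params()] object with attributes `loglik`,
#'   `converged`, `method` and `n`.
#' @export
fit_exgauss_mle <- function(x, min_n = 8) {
  x <- as.numeric(x)
  if (anyNA(x) || !all(is.finite(x)))
    stop("fit_exgauss_mle: durations must be finite", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("fit_exgauss_mle: need at least %d observations, got %d",
                 min_n, length(x)), call. = FALSE)
  nll <- function(par) {
    v <- -sum(dexgauss(x, par[1], par[2], par[3], log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  init <- .exg_init(x)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(-Inf, 1e-3, 1e-3),
                      control = list(maxit = 500))
  .exg_fit_result(opt$par, -opt$value, opt$convergence == 0, "mle", length(x))
}

#' Fit an ex-Gaussian distribution by quantile maximum probability
#'
#' Estimates the parameters by maximizing the multinomial probability of
#' the observed inter-quantile counts: the sample is partitioned by its
#' empirical quantiles into `n_quantiles + 1` bins and the parameters are
#' chosen to maximize `sum(count_i * log P(bin_i))` under the ex-Gaussian
#' cdf. This quantile-based estimator mirrors the behaviour of quantile
#' maximum probability estimation tools used for response-time
#' distributions and is more robust to stray observations than raw MLE.
#'
#' @param x Observed durations (ms).
#' @param n_quantiles Number of interior quantiles (default 9, i.e. deciles).
#' @return Same contract as [fit_exgauss_mle()].
#' @export
fit_exgauss_quantile <- function(x, n_quantiles = 9) {
  x <- as.numeric(x)
  if (anyNA(x) || !all(is.finite(x)))
    stop("fit_exgauss_quantile: durations must be finite", call. = FALSE)
  if (n_quantiles < 1)
    stop("fit_exgauss_quantile: n_quantiles must be >= 1", call. = FALSE)
  if (length(x) < n_quantiles + 1)
    stop(sprintf(paste0("fit_exgauss_quantile: need at least n_quantiles + 1",
                        " = %d observations, got %d"),
                 n_quantiles + 1, length(x)), call. = FALSE)
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  edges <- stats::quantile(x, probs = probs, names = FALSE)
  counts <- tabulate(findInterval(x, vec = edges, left.open = TRUE) + 1L,
                     nbins = n_quantiles + 1L)
  nll <- function(par) {
    cdf <- pexgauss(edges, par[1], par[2], par[3])
    p <- diff(c(0, cdf, 1))
    v <- -sum(counts * log(pmax(p, 1e-300)))
    if (!is.finite(v)) 1e10 else v
  }
  init <- .exg_init(x)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(-Inf, 1e-3, 1e-3),
                      control = list(maxit = 500))
  .exg_fit_result(opt$par, -opt$value, opt$convergence == 0,
                  "quantile", length(x))
}
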