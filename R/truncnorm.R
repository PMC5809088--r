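## Truncated-normal machinery shared by the Gibbs imputer, QRILC and kNN-TN.
## Sampling uses the inverse-CDF method so draws are a deterministic function
## of the uniform stream (no rejection loops).

check_tn_params <- function(mu, sigma, lo, hi) {
  if (any(!is.finite(mu))) stop("mu must be finite", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive", call. = FALSE)
  if (any(is.na(lo)) || any(is.na(hi)) || any(lo >= hi))
    stop("truncation bounds must satisfy lo < hi", call. = FALSE)
  invisible(TRUE)
}

# log(1 - exp(x)) for x <= 0, stable near both ends
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# standardized truncated-normal quantile; a, b may be +-Inf.
# Reflects into the left tail so log-space pnorm/qnorm stay accurate when
# the interval sits far out in one tail.
qtnorm_std <- function(p, a, b) {
  flip <- (a + b) > 0
  flip[is.na(flip)] <- FALSE  # a = -Inf, b = Inf: symmetric, no reflection
  a2 <- ifelse(flip, -b, a)
  b2 <- ifelse(flip, -a, b)
  p2 <- ifelse(flip, 1 - p, p)
  la <- stats::pnorm(a2, log.p = TRUE)       # -Inf when a2 = -Inf
  lb <- stats::pnorm(b2, log.p = TRUE)
  # log[ Phi(a2) + p2 (Phi(b2) - Phi(a2)) ]
  ldiff <- lb + log1mexp(pmin(la - lb, 0))
  lmix <- ifelse(is.infinite(la) & la < 0,
                 log(p2) + ldiff,
                 la + log1p(exp(log(p2) + ldiff - la)))
  lmix[p2 == 0] <- la[p2 == 0]
  z <- stats::qnorm(lmix, log.p = TRUE)
  # guard against round-off pushing the quantile outside [a2, b2]
  z <- pmin(pmax(z, a2), b2)
  ifelse(flip, -z, z)
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampling from N(mu, sigma^2) restricted to \[lo, hi\].
#' `mu` (and `sigma`, `lo`, `hi`) may be vectors recycled against `n`,
#' which is how the Gibbs imputer draws one value per missing element.
#'
#' @param n Number of draws.
#' @param mu,sigma Location and scale of the parent normal.
#' @param lo,hi Truncation bounds; `-Inf` / `Inf` allowed.
#' @return Numeric vector of length `n`, every element in \[lo, hi\].
#' @examples
#' set.seed(1)
#' x <- sample_truncated_normal(1000, mu = 0, sigma = 1, lo = 0)
#' mean(x)  # close to sqrt(2/pi)
#' @export
sample_truncated_normal <- function(n, mu, sigma, lo = -Inf, hi = Inf) {
  stopifnot(length(n) == 1L, n >= 1)
  check_tn_params(mu, sigma, lo, hi)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  a <- (rep_len(lo, n) - mu) / sigma
  b <- (rep_len(hi, n) - mu) / sigma
  u <- stats::runif(n)
  mu + sigma * qtnorm_std(u, a, b)
}

#' Truncated normal distribution function
#'
#' CDF of N(mu, sigma^2) truncated to \[lo, hi\]; used for goodness-of-fit
#' checks on the sampler.
#'
#' @param q Quantiles.
#' @inheritParams sample_truncated_normal
#' @return P(X <= q) under the truncated distribution.
#' @export
ptruncnorm <- function(q, mu = 0, sigma = 1, lo = -Inf, hi = Inf) {
  check_tn_params(mu, sigma, lo, hi)
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- (q - mu) / sigma
  num <- stats::pnorm(pmin(pmax(z, a), b)) - stats::pnorm(a)
  den <- stats::pnorm(b) - stats::pnorm(a)
  pmin(pmax(num / den, 0), 1)
}

# xf(x) terms with phi(+-Inf) treated as exact zeros
phi0 <- function(x) ifelse(is.infinite(x), 0, stats::dnorm(x))
xphi0 <- function(x) ifelse(is.infinite(x), 0, x * stats::dnorm(x))

tn_loglik <- function(theta, x, lo, hi) {
  mu <- theta[1]; sigma <- exp(theta[2])
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- (x - mu) / sigma
  lz <- stats::pnorm(b) - stats::pnorm(a)
  if (lz <= 0) return(-Inf)
  sum(stats::dnorm(z, log = TRUE)) - length(x) * log(sigma) -
    length(x) * log(lz)
}

tn_grad <- function(theta, x, lo, hi) {
  mu <- theta[1]; sigma <- exp(theta[2])
  n <- length(x)
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- (x - mu) / sigma
  zmass <- stats::pnorm(b) - stats::pnorm(a)
  d_mu <- (sum(z) + n * (phi0(b) - phi0(a)) / zmass) / sigma
  d_sigma <- (sum(z^2) - n + n * (xphi0(b) - xphi0(a)) / zmass) / sigma
  c(d_mu, d_sigma * sigma)  # chain rule for log-sigma parameterization
}

#' Maximum-likelihood fit of a truncated normal with known bounds
#'
#' Estimates the location and scale of the parent normal from samples that
#' were observed only inside \[lo, hi\] (for left-censored variables the
#' observed values are truncated below at the detection limit).
#' Newton-Raphson on (mu, log sigma) with the analytic gradient and a
#' finite-difference Hessian; falls back to Nelder-Mead if the Newton
#' iteration leaves the likelihood surface.
#'
#' @param samples Numeric vector, at least 10 finite values inside the
#'   bounds with at least 2 distinct values.
#' @param lo,hi Known truncation bounds (`-Inf` / `Inf` allowed).
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Maximum Newton iterations.
#' @return A list with elements `mu`, `sigma`, `lo`, `hi`, `loglik`,
#'   `iterations`, `converged`.
#' @export
truncnorm_mle <- function(samples, lo = -Inf, hi = Inf,
                          tol = 1e-8, max_iter = 100) {
  x <- samples[is.finite(samples)]
  if (length(x) < 10)
    stop("truncated-normal MLE needs at least 10 finite samples", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate data: all samples identical", call. = FALSE)
  if (any(x < lo) || any(x > hi))
    stop("samples must lie within [lo, hi]", call. = FALSE)
  n <- length(x)
  theta <- c(mean(x), log(sqrt(mean((x - mean(x))^2))))
  ok <- TRUE
  iter <- 0L
  repeat {
    g <- tn_grad(theta, x, lo, hi)
    if (!all(is.finite(g))) { ok <- FALSE; break }
    if (sqrt(sum(g^2)) < tol || iter >= max_iter) break
    # numeric Hessian of the analytic gradient (central differences)
    h <- 1e-5
    H <- matrix(0, 2, 2)
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      H[, k] <- (tn_grad(theta + e, x, lo, hi) -
                 tn_grad(theta - e, x, lo, hi)) / (2 * h)
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) { ok <- FALSE; break }
    cand <- theta - step
    # backtrack if the full Newton step lowers the likelihood
    ll0 <- tn_loglik(theta, x, lo, hi)
    shrink <- 0L
    while (tn_loglik(cand, x, lo, hi) < ll0 && shrink < 30L) {
      step <- step / 2
      cand <- theta - step
      shrink <- shrink + 1L
    }
    if (shrink >= 30L) { ok <- FALSE; break }
    theta <- cand
    iter <- iter + 1L
  }
  converged <- ok && sqrt(sum(tn_grad(theta, x, lo, hi)^2)) < max(tol, 1e-6)
  if (!converged) {
    fb <- stats::optim(theta, function(th) -tn_loglik(th, x, lo, hi),
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (fb$convergence != 0)
      stop("truncated-normal MLE failed to converge", call. = FALSE)
    theta <- fb$par
    converged <- TRUE
  }
  list(mu = theta[1], sigma = exp(theta[2]), lo = lo, hi = hi,
       loglik = tn_loglik(theta, x, lo, hi),
       iterations = iter, converged = converged)
}

#' Estimate normal parameters of a left-censored variable by quantile
#' regression
#'
#' Given the observed (upper) part of a left-censored variable and the
#' fraction censored, regresses the sorted observed values on the
#' standard-normal quantiles of their plotting positions.  The plotting
#' position of the r-th smallest of f observed values accounts for the
#' censored lower tail: p_r = missing_fraction + (1 - missing_fraction) *
#' r / (f + 1).  The OLS intercept and slope estimate the mean and SD of
#' the underlying complete normal.
#'
#' @param observed Numeric vector of observed (non-missing) values.
#' @param missing_fraction Fraction of the variable that is censored,
#'   in \[0, 1).
#' @return A list with `mu`, `sigma`, `lo = -Inf`, `hi = min(observed)`.
#' @export
censored_quantile_estimate <- function(observed, missing_fraction = 0) {
  x <- observed[is.finite(observed)]
  if (length(x) < 3)
    stop("censored quantile estimation needs at least 3 observed values",
         call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  f <- length(x)
  p <- missing_fraction + (1 - missing_fraction) * seq_len(f) / (f + 1)
  q <- stats::qnorm(p)
  fit <- stats::lm.fit(cbind(1, q), sort(x))
  sigma <- fit$coefficients[2]
  if (!is.finite(sigma) || sigma <= 0)
    stop("censored quantile estimation produced a non-positive scale",
         call. = FALSE)
  list(mu = unname(fit$coefficients[1]), sigma = unname(sigma),
       lo = -Inf, hi = min(x))
}
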