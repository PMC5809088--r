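# Fixture builders shared across the test files.  All randomness is
# seeded by the caller.

# Small correlated two-group dataset with an MNAR mask applied.
make_censored_fixture <- function(n_per_group = 20, p = 10,
                                  proportion = 0.4, seed = 101,
                                  cutoff_lo = 0.3, cutoff_hi = 0.6) {
  sim <- simulate_two_group_dataset(n_per_group = n_per_group, p = p,
                                    seed = seed)
  cen <- generate_mnar_mask(sim$data,
                            mnar_spec(proportion, cutoff_lo, cutoff_hi),
                            seed = seed + 1L)
  list(sim = sim, censored = cen$censored, cutoffs = cen$cutoffs,
       missing_vars = cen$missing_vars)
}

# Plain matrix with NAs at given positions.
na_matrix <- function(values, na_cells = NULL) {
  if (!is.null(na_cells)) values[na_cells] <- NA_real_
  data_matrix(values)
}

# Closed-form glmnet ridge fitted values (alpha = 0): predictors
# standardized by their 1/n SDs, response standardized internally by its
# 1/n SD, unpenalized intercept.
ridge_oracle_fitted <- function(y, X, lambda) {
  n <- length(y)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  yc <- y - mean(y)
  sdy <- sqrt(mean(yc^2))
  beta_s <- solve(crossprod(Xs) / n + (lambda / sdy) * diag(ncol(X)),
                  crossprod(Xs, yc) / n)
  drop(mean(y) + Xs %*% beta_s)
}

# Brute-force Procrustes: numeric minimization over rotation angle,
# reflection, isotropic scale and translation (2-D configurations).
procrustes_brute_force <- function(ref, tgt) {
  sse_at <- function(par, reflect) {
    th <- par[1]; s <- par[2]; tx <- par[3]; ty <- par[4]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    if (reflect) R <- R %*% diag(c(1, -1))
    moved <- s * tgt %*% R
    moved <- sweep(moved, 2, c(-tx, -ty))
    sum((moved - ref)^2)
  }
  best <- Inf
  for (reflect in c(FALSE, TRUE)) {
    for (th0 in seq(0, 2 * pi, length.out = 9)) {
      o <- stats::optim(c(th0, 1, 0, 0), sse_at, reflect = reflect,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
      best <- min(best, o$value)
    }
  }
  best
}

# Dense grid search maximizing the truncated-normal log-likelihood.
tn_grid_oracle <- function(x, lo, hi, mu_range, sigma_range, steps = 80) {
  grid <- expand.grid(mu = seq(mu_range[1], mu_range[2], length.out = steps),
                      ls = seq(log(sigma_range[1]), log(sigma_range[2]),
                               length.out = steps))
  ll <- mapply(function(m, s) censimp:::tn_loglik(c(m, s), x, lo, hi),
               grid$mu, grid$ls)
  list(mu = grid$mu[which.max(ll)], sigma = exp(grid$ls[which.max(ll)]),
       loglik = max(ll))
}
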