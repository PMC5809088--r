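test_that("missing variables are ordered by ascending missing count with index tie-break", {
  vals <- matrix(rnorm(40), 10, 4)
  vals[1:3, 2] <- NA; vals[1, 3] <- NA; vals[4:6, 4] <- NA
  expect_equal(order_missing_variables(data_matrix(vals)), c(3L, 2L, 4L))
  expect_equal(order_missing_variables(data_matrix(matrix(rnorm(12), 4, 3))),
               integer(0))
  vals2 <- matrix(rnorm(12), 4, 3); vals2[1, 2] <- NA
  expect_equal(order_missing_variables(data_matrix(vals2)), 2L)
})

test_that("half-min initialization fills half the column minimum; complete input unchanged", {
  vals <- matrix(c(2, 4, 8, NA, NA, 1, 2, 3, 4, 5), 5, 2)
  init <- initialize_missing(data_matrix(vals), "half_min")
  expect_equal(unname(init$values[4:5, 1]), c(1, 1))
  complete <- data_matrix(matrix(rnorm(20), 5, 4))
  expect_equal(initialize_missing(complete, "half_min")$values,
               complete$values)
})

test_that("QRILC initialization stays below each variable's observed minimum", {
  fx <- make_censored_fixture(seed = 41)
  init <- initialize_missing(fx$censored, "qrilc", seed = 4)
  for (j in fx$missing_vars) {
    mi <- fx$censored$mask[, j]
    expect_true(all(init$values[mi, j] < min(fx$censored$values[!mi, j])))
  }
})

test_that("elastic net interpolates exact linear relations at lambda = 0", {
  set.seed(42)
  X <- matrix(rnorm(30), 10, 3)
  y <- 2 * X[, 2] - 1
  expect_lt(max(abs(fit_predict_elastic_net(y, X, lambda = 0) - y)), 1e-6)
})

test_that("pure ridge matches the closed-form solution of the documented penalty mapping", {
  set.seed(43)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, -2, 0.5) + rnorm(10, sd = 0.3))
  for (lambda in c(0.05, 0.3, 1)) {
    expect_lt(max(abs(fit_predict_elastic_net(y, X, lambda, alpha = 0) -
                      ridge_oracle_fitted(y, X, lambda))), 1e-4)
  }
})

test_that("elastic net handles constant response and single-predictor input", {
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(fit_predict_elastic_net(rep(2, 10), X), rep(2, 10))
  y <- rnorm(10)
  expect_length(fit_predict_elastic_net(y, X[, 1, drop = FALSE]), 10)
})

test_that("missing-part RMSD follows its definition", {
  expect_equal(rmsd_missing(c(1, 2, 3), c(1, 2, 3), c(1, 3)), 0)
  expect_equal(rmsd_missing(c(2, 0), c(1, 1), c(1, 2)), 1)
  expect_equal(rmsd_missing(c(0, 5), c(0, 8), 2), 3)
  expect_error(rmsd_missing(1:3, 1:3, integer(0)), "nonempty")
})

test_that("Gibbs updates respect bounds, keep observed entries, and trace every cycle", {
  set.seed(44)
  n <- 30
  X_other <- matrix(rnorm(n * 4), n, 4)
  y_true <- drop(X_other %*% c(1, 0.5, -1, 0.2) + rnorm(n, sd = 0.4))
  mi <- which(y_true < quantile(y_true, 0.3))
  hi <- min(y_true[-mi])
  y_work <- y_true; y_work[mi] <- hi - 0.5
  state <- list(y_prime = y_work, missing_index = mi, lo = -Inf, hi = hi)
  out <- gibbs_update_variable(state, X_other, iters_each = 25,
                               trace_rows = mi[1])
  expect_true(all(out$state$y_prime[mi] <= hi))
  expect_identical(out$state$y_prime[-mi], y_true[-mi])
  expect_equal(nrow(out$trace), 25L)
  expect_true(all(out$trace$y_tilde <= hi))
})

test_that("with no truncation the Gibbs draws match the untruncated normal", {
  set.seed(45)
  n <- 60
  X_other <- matrix(rnorm(n * 3), n, 3)
  y <- drop(X_other %*% c(2, -1, 0.5) + rnorm(n, sd = 0.1))
  mi <- 1:12
  state <- list(y_prime = y, missing_index = mi, lo = -Inf, hi = Inf)
  # burn in, then collect repeated draws of one element at the converged
  # (y_hat, sigma)
  out <- gibbs_update_variable(state, X_other, iters_each = 20)
  draws <- replicate(500, {
    st <- gibbs_update_variable(out$state, X_other, iters_each = 1)$state
    st$y_prime[mi[1]]
  })
  # every replicate starts from the same state, so each draw comes from
  # N(y_hat, sigma^2) at the parameters one fresh cycle would compute
  fit <- fit_predict_elastic_net(out$state$y_prime, X_other)
  sig <- rmsd_missing(fit, out$state$y_prime, mi)
  ks <- suppressWarnings(stats::ks.test(draws, "pnorm", mean = fit[mi[1]],
                                        sd = sig))
  expect_gt(ks$p.value, 1e-4)
})

test_that("gsimp conserves observed cells and respects truncation bounds", {
  fx <- make_censored_fixture(seed = 46)
  cfg <- run_config(iters_each = 8, iters_all = 3, seed = 9)
  res <- impute_gsimp(fx$censored, config = cfg)
  b <- truncation_bounds(fx$censored)
  for (j in fx$missing_vars) {
    mi <- fx$censored$mask[, j]
    expect_identical(res$matrix$values[!mi, j], fx$censored$values[!mi, j])
    expect_true(all(res$matrix$values[mi, j] <= b$hi[j]))
  }
  expect_equal(n_missing(res$matrix), 0L)
  expect_equal(res$cycles_per_variable, 24L)
})

test_that("gsimp is deterministic under a fixed seed, for serial and parallel runs", {
  fx <- make_censored_fixture(n_per_group = 15, p = 8, seed = 47)
  cfg1 <- run_config(iters_each = 5, iters_all = 2, seed = 21)
  r1 <- impute_gsimp(fx$censored, config = cfg1)
  r2 <- impute_gsimp(fx$censored, config = cfg1)
  expect_identical(r1$matrix$values, r2$matrix$values)

  cfg2 <- run_config(iters_each = 5, iters_all = 2, seed = 21, workers = 2)
  cfg3 <- run_config(iters_each = 5, iters_all = 2, seed = 21, workers = 3)
  p2 <- impute_gsimp(fx$censored, config = cfg2)
  p3 <- impute_gsimp(fx$censored, config = cfg3)
  expect_identical(p2$matrix$values, p3$matrix$values)

  cfg_other <- run_config(iters_each = 5, iters_all = 2, seed = 22)
  r3 <- impute_gsimp(fx$censored, config = cfg_other)
  expect_false(identical(r1$matrix$values, r3$matrix$values))
})

test_that("a complete matrix is returned unchanged with a warning", {
  m <- data_matrix(matrix(rnorm(40), 10, 4))
  expect_warning(res <- impute_gsimp(m), "no missing")
  expect_identical(res$matrix$values, m$values)
})

test_that("trace length equals iters_each * iters_all for a tracked cell", {
  fx <- make_censored_fixture(n_per_group = 12, p = 6, seed = 48)
  j <- fx$missing_vars[1]
  i <- which(fx$censored$mask[, j])[1]
  cfg <- run_config(iters_each = 7, iters_all = 4, seed = 2)
  res <- impute_gsimp(fx$censored, config = cfg,
                      trace_cells = cbind(i, j))
  expect_equal(nrow(res$traces), 28L)
  expect_equal(res$traces$cycle, 1:28)
  # final imputed value is the last Gibbs draw
  expect_equal(res$matrix$values[i, j], res$traces$y_tilde[28])
})
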