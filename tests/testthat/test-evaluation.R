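test_that("NRMSE follows its definition and is scale-invariant", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-10)
  expect_error(nrmse(c(2, 2, 2), c(1, 2, 3)), "variance")
  set.seed(71)
  t0 <- rnorm(30); x0 <- rnorm(30)
  for (ab in list(c(2, 5), c(-3, 1), c(0.01, -4))) {
    expect_equal(nrmse(ab[1] * t0 + ab[2], ab[1] * x0 + ab[2]),
                 nrmse(t0, x0), tolerance = 1e-10)
  }
})

test_that("sum of ranks sums per-variable method ranks with average-rank ties", {
  tab <- rbind(c(0.2, 0.5), c(0.1, 0.9))
  expect_equal(unname(sum_of_ranks(tab)), c(2, 4))
  k <- 5
  tab2 <- cbind(seq(0.1, 0.5, length.out = k),
                seq(0.2, 0.6, length.out = k),
                seq(0.3, 0.7, length.out = k))
  expect_equal(unname(sum_of_ranks(tab2)), c(k, 2 * k, 3 * k))
  tie <- rbind(c(0.3, 0.3))
  expect_equal(unname(sum_of_ranks(tie)), c(1.5, 1.5))
  # rank conservation: totals equal k * m(m+1)/2
  set.seed(72)
  tab3 <- matrix(runif(28), 7, 4)
  expect_equal(sum(sum_of_ranks(tab3)), 7 * 4 * 5 / 2)
  expect_error(sum_of_ranks(rbind(c(1, NA))), "finite")
})

test_that("PCA scores are centred and reconstruct exact low-rank data", {
  set.seed(73)
  basis <- matrix(rnorm(10 * 2), 10, 2)
  load <- matrix(rnorm(2 * 6), 2, 6)
  vals <- basis %*% load
  pc <- stats::prcomp(vals, center = TRUE)
  sc <- ordination_scores(data_matrix(vals), mode = "pca", n_components = 2)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  recon <- sc %*% t(pc$rotation[, 1:2])
  expect_lt(max(abs(recon - scale(vals, scale = FALSE))), 1e-8)
})

test_that("PLS latent variables track a perfectly predictive variable", {
  set.seed(74)
  labels <- rep(c(0, 1), each = 20)
  vals <- cbind(5 * labels + rnorm(40, sd = 0.01),
                matrix(rnorm(40 * 4, sd = 0.3), 40, 4))
  sc <- ordination_scores(data_matrix(vals), labels, "pls", 2)
  expect_gt(abs(cor(sc[, 1], labels)), 0.99)
  expect_error(ordination_scores(data_matrix(vals), mode = "pls"), "labels")
  expect_error(ordination_scores(data_matrix(vals), labels, "pls",
                                 n_components = 50), "n_components")
})

test_that("Procrustes error vanishes under similarity transforms and matches brute force", {
  set.seed(75)
  ref <- matrix(rnorm(8), 4, 2)
  expect_equal(procrustes_sse(ref, ref), 0, tolerance = 1e-12)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(1.7 * ref %*% R, 2, c(3, -2), "+")
  expect_equal(procrustes_sse(ref, moved), 0, tolerance = 1e-10)

  tgt <- ref + matrix(rnorm(8, sd = 0.3), 4, 2)
  expect_equal(procrustes_sse(ref, tgt), procrustes_brute_force(ref, tgt),
               tolerance = 1e-6)
  expect_error(procrustes_sse(ref, matrix(0, 4, 2)), "degenerate")
})

test_that("log p-value correlation matches a step-by-step recomputation", {
  set.seed(76)
  sim <- simulate_two_group_dataset(n_per_group = 80, p = 10, seed = 76)
  cen <- generate_mnar_mask(sim$data, mnar_spec(0.4, 0.3, 0.6), seed = 77)
  imp <- impute_hm(cen$censored)
  mv <- cen$missing_vars
  r <- pvalue_log_correlation(sim$data, imp, sim$labels, mv)
  # independent recomputation
  g <- sim$labels
  p_o <- sapply(mv, function(j) t.test(sim$data$values[, j] ~ g)$p.value)
  p_i <- sapply(mv, function(j) t.test(imp$values[, j] ~ g)$p.value)
  expect_equal(r, cor(log(p_o), log(p_i)), tolerance = 1e-10)
  expect_equal(pvalue_log_correlation(sim$data, sim$data, sim$labels, mv), 1)
  expect_error(pvalue_log_correlation(sim$data, imp, sim$labels, mv[1:2]),
               "at least 3")
})

test_that("TPR counts recovered significant variables", {
  expect_equal(true_positive_rate(c(0.01, 0.02, 0.2), c(0.01, 0.3, 0.01),
                                  0.05), 0.5)
  p <- runif(10, 0, 0.04)
  expect_equal(true_positive_rate(p, p, 0.05), 1)
  expect_error(true_positive_rate(c(0.5, 0.9), c(0.01, 0.01), 0.05),
               "undefined")
  # monotone in the overlap
  p_o <- c(0.01, 0.02, 0.03, 0.5)
  tpr_vals <- sapply(0:3, function(h)
    true_positive_rate(p_o, c(rep(0.01, h), rep(0.9, 4 - h)), 0.05))
  expect_true(all(diff(tpr_vals) >= 0))
})

test_that("a perfect imputation scores the ideal value on every metric", {
  set.seed(78)
  sim <- simulate_two_group_dataset(n_per_group = 20, p = 8, seed = 78)
  cen <- generate_mnar_mask(sim$data, mnar_spec(0.5, 0.3, 0.6), seed = 79)
  mv <- cen$missing_vars
  # evaluate HM against the truth, then check the cheating route by hand
  o <- sim$data; imp_cheat <- sim$data
  nr <- sapply(mv, function(j) {
    idx <- cen$censored$mask[, j]
    nrmse(o$values[idx, j], imp_cheat$values[idx, j])
  })
  expect_true(all(nr == 0))
  expect_equal(procrustes_sse(ordination_scores(o, mode = "pca"),
                              ordination_scores(imp_cheat, mode = "pca")),
               0, tolerance = 1e-10)
  p_o <- sapply(seq_len(8), function(j)
    t.test(o$values[, j] ~ sim$labels)$p.value)
  expect_equal(true_positive_rate(p_o, p_o, 0.5), 1)
})

test_that("the evaluation pipeline assembles all metrics and tolerates method failure", {
  fx <- make_censored_fixture(n_per_group = 25, p = 10, proportion = 0.4,
                              seed = 80)
  cfg <- run_config(iters_each = 4, iters_all = 2, seed = 6)
  rep <- suppressWarnings(
    evaluate_methods(fx$sim$data, fx$censored, labels = fx$sim$labels,
                     methods = c("gsimp", "qrilc", "hm"), config = cfg))
  m <- ncol(rep$nrmse); k <- nrow(rep$nrmse)
  expect_equal(k, length(fx$missing_vars))
  expect_equal(sum(rep$sor), k * m * (m + 1) / 2)
  expect_true(all(is.finite(rep$nrmse)))
  expect_equal(nrow(rep$procrustes), 3L)
  expect_true(all(rep$procrustes$pca_sse >= 0))
  expect_true(all(is.finite(rep$procrustes$pls_sse)))
  expect_true(all(rep$p_correlation >= -1 & rep$p_correlation <= 1))
  if (!is.null(rep$tpr)) expect_true(all(rep$tpr >= 0 & rep$tpr <= 1,
                                         na.rm = TRUE))

  # pipeline determinism under a fixed seed
  rep2 <- suppressWarnings(
    evaluate_methods(fx$sim$data, fx$censored, labels = fx$sim$labels,
                     methods = c("gsimp", "qrilc", "hm"), config = cfg))
  expect_identical(rep$nrmse, rep2$nrmse)
  expect_identical(rep$sor, rep2$sor)
})
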