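## Synthetic two-group data with a preserved covariance structure, and
## MNAR masks produced by per-variable quantile censoring.

#' MNAR censoring specification
#'
#' @param missing_proportion Fraction of variables to censor, in (0, 1).
#' @param cutoff_lo,cutoff_hi Endpoints of the uniform distribution the
#'   per-variable quantile cut-off is drawn from.
#' @return A list of class `mnar_spec`.
#' @export
mnar_spec <- function(missing_proportion, cutoff_lo = 0.3, cutoff_hi = 0.6) {
  stopifnot(missing_proportion > 0, missing_proportion < 1,
            cutoff_lo > 0, cutoff_hi < 1, cutoff_lo < cutoff_hi)
  structure(list(missing_proportion = missing_proportion,
                 cutoff_lo = cutoff_lo, cutoff_hi = cutoff_hi),
            class = "mnar_spec")
}

#' Random correlation matrix with moderate structure
#'
#' Builds a symmetric positive-definite matrix with unit diagonal from
#' random orthogonal eigenvectors and eigenvalues spread to keep the
#' condition number at most 100.  A desk-scale stand-in for the covariance
#' of a real metabolomics panel when none is supplied.
#'
#' @param p Dimension (at least 2).
#' @param seed Optional integer seed.
#' @return A p x p correlation matrix.
#' @export
random_covariance <- function(p, seed = NULL) {
  stopifnot(p >= 2)
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
  ev <- exp(seq(log(1), log(40), length.out = p))  # condition number 40
  A <- Q %*% (ev * t(Q))
  A <- (A + t(A)) / 2
  A <- stats::cov2cor(A)
  # unit-diagonal shrinkage toward identity until well conditioned
  repeat {
    e <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(e) > 0 && max(e) / min(e) <= 100) break
    A <- (A + 0.1 * diag(p)) / 1.1
  }
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- NULL
  A
}

# MVN draws factorizing the covariance as U sqrt(D) U' (the SVD of a
# PSD symmetric matrix coincides with its eigendecomposition)
rmvnorm_svd <- function(n, mean, covariance) {
  p <- length(mean)
  ed <- eigen(covariance, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values)))
    stop("covariance is not positive semi-definite", call. = FALSE)
  R <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% R, 2, mean, "+")
}

#' Simulate a two-group dataset with a shared covariance
#'
#' Emulates a two-condition metabolomics study: for each group a p-vector
#' of variable means is drawn i.i.d. N(0, mean_sd^2), then `n_per_group`
#' observations are drawn from the multivariate normal with those means
#' and the common covariance (factorized by SVD).  The groups are stacked
#' row-wise, so group differences exist while the correlation structure
#' is preserved.  Defaults give a 160 x 76 matrix (80 observations per
#' group, 76 variables, mean SD 0.5).
#'
#' @param n_per_group Observations per group (>= 2).
#' @param covariance p x p symmetric positive semi-definite matrix;
#'   default [random_covariance()] of dimension `p`.
#' @param p Number of variables (used only when `covariance` is NULL).
#' @param mean_sd SD of the normal the per-variable group means are drawn
#'   from.
#' @param seed Optional integer seed.
#' @return A list of class `simulated_dataset`: `data` (complete
#'   [data_matrix()]), `labels` (factor of length 2*n_per_group),
#'   `group_means` (2 x p), `covariance`.
#' @export
simulate_two_group_dataset <- function(n_per_group = 80, covariance = NULL,
                                       p = 76, mean_sd = 0.5, seed = NULL) {
  stopifnot(n_per_group >= 2, mean_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariance)) covariance <- random_covariance(p)
  covariance <- as.matrix(covariance)
  p <- ncol(covariance)
  if (nrow(covariance) != p || max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be square and symmetric", call. = FALSE)
  group_means <- matrix(stats::rnorm(2 * p, 0, mean_sd), nrow = 2)
  blocks <- lapply(1:2, function(g)
    rmvnorm_svd(n_per_group, group_means[g, ], covariance))
  vals <- do.call(rbind, blocks)
  labels <- factor(rep(c("A", "B"), each = n_per_group))
  dm <- data_matrix(vals,
                    row_ids = paste0(rep(c("A", "B"), each = n_per_group),
                                     "_", rep(seq_len(n_per_group), 2)),
                    col_ids = paste0("var_", seq_len(p)))
  structure(list(data = dm, labels = labels, group_means = group_means,
                 covariance = covariance),
            class = "simulated_dataset")
}

#' Censor a complete matrix missing-not-at-random
#'
#' Selects `round(missing_proportion * p)` variables uniformly at random;
#' for each, draws a quantile cut-off q ~ U(cutoff_lo, cutoff_hi) and
#' masks every element strictly below the variable's empirical q-quantile
#' (type-7).  This reproduces detection-limit censoring: only the low end
#' of a variable goes missing.
#'
#' @param matrix A complete [data_matrix()].
#' @param spec An [mnar_spec()].
#' @param seed Optional integer seed.
#' @return A list: `censored` ([data_matrix()] with mask set), `cutoffs`
#'   (named numeric vector of the applied thresholds), `missing_vars`
#'   (column indices censored).
#' @export
generate_mnar_mask <- function(matrix, spec, seed = NULL) {
  m <- as_data_matrix(matrix)
  stopifnot(inherits(spec, "mnar_spec"))
  if (n_missing(m) > 0) stop("input matrix must be complete", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(m$values)
  n_miss <- round(spec$missing_proportion * p)
  if (n_miss < 1)
    stop("missing_proportion * p rounds to zero variables", call. = FALSE)
  vars <- sort(sample.int(p, n_miss))
  q <- stats::runif(n_miss, spec$cutoff_lo, spec$cutoff_hi)
  vals <- m$values
  cutoffs <- numeric(n_miss)
  for (i in seq_along(vars)) {
    j <- vars[i]
    cutoffs[i] <- unname(stats::quantile(vals[, j], q[i], type = 7))
    vals[vals[, j] < cutoffs[i], j] <- NA_real_
  }
  names(cutoffs) <- m$col_ids[vars]
  list(censored = data_matrix(vals, m$row_ids, m$col_ids),
       cutoffs = cutoffs, missing_vars = vars)
}
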