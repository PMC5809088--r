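#' Run configuration for the imputation methods
#'
#' Bundles the tuning parameters shared by the imputers.  The defaults are
#' the recommended settings for the Gibbs imputer: 20 outer passes over the
#' matrix and 100 Gibbs cycles per missing variable within each pass
#' (2000 cycles per variable in total), elastic-net penalty `lambda = 0.01`
#' with mixing `alpha = 0.5`, QRILC initialization, and truncation bounds
#' of (-Inf, per-variable observed minimum\].
#'
#' @param iters_each Gibbs cycles per missing variable within one outer
#'   pass.
#' @param iters_all Outer passes over the whole matrix.
#' @param lambda Elastic-net penalty weight (glmnet scale, i.e. on the
#'   1/(2n)-averaged squared-error objective).
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (0 = ridge,
#'   1 = lasso).
#' @param initialization `"qrilc"` or `"half_min"` starting fill.
#' @param lo_policy Lower truncation bound: `"neg_inf"` for centred or
#'   log-scale data, `"zero"` for raw positive abundances.
#' @param hi_policy Upper truncation bound: `"min_observed"` (default),
#'   `"quantile"` (uses `hi_q`), or `"fixed_loq"` (uses `loq`).
#' @param hi_q Quantile for `hi_policy = "quantile"`.
#' @param loq Numeric vector of per-variable limits of quantification for
#'   `hi_policy = "fixed_loq"`.
#' @param workers Number of parallel workers.  With `workers > 1`, within
#'   each outer pass every missing variable is updated against a frozen
#'   snapshot of the matrix and all columns are committed together, so
#'   results do not depend on the worker count.
#' @param seed Integer seed controlling all randomness.
#' @param tune_sigma Multiplier on the QRILC scale estimate.
#' @param k Neighbour count for kNN-TN.
#' @return A list of class `run_config`.
#' @export
run_config <- function(iters_each = 100, iters_all = 20,
                       lambda = 0.01, alpha = 0.5,
                       initialization = c("qrilc", "half_min"),
                       lo_policy = c("neg_inf", "zero"),
                       hi_policy = c("min_observed", "quantile", "fixed_loq"),
                       hi_q = 0.5, loq = NULL,
                       workers = 1L, seed = 1L,
                       tune_sigma = 1, k = 10L) {
  stopifnot(iters_each >= 1, iters_all >= 1, lambda >= 0,
            alpha >= 0, alpha <= 1, workers >= 1, tune_sigma > 0, k >= 1)
  structure(list(
    iters_each = as.integer(iters_each), iters_all = as.integer(iters_all),
    lambda = lambda, alpha = alpha,
    initialization = match.arg(initialization),
    lo_policy = match.arg(lo_policy),
    hi_policy = match.arg(hi_policy),
    hi_q = hi_q, loq = loq,
    workers = as.integer(workers), seed = as.integer(seed),
    tune_sigma = tune_sigma, k = as.integer(k)
  ), class = "run_config")
}

#' Per-variable truncation bounds for left-censored imputation
#'
#' Builds the length-p lower and upper limit vectors used by the Gibbs
#' imputer.  Variables without missing values get (-Inf, Inf) so they are
#' never constrained.  For missing variables the upper limit defaults to
#' the observed minimum (the natural proxy for the detection limit), or a
#' quantile of the observed values, or a supplied LOQ; the lower limit is
#' -Inf (centred/log data) or 0 (raw positive data).
#'
#' @param matrix A [data_matrix()].
#' @param lo_policy,hi_policy,hi_q,loq See [run_config()].
#' @return A list with numeric vectors `lo` and `hi` of length p.
#' @export
truncation_bounds <- function(matrix,
                              lo_policy = c("neg_inf", "zero"),
                              hi_policy = c("min_observed", "quantile", "fixed_loq"),
                              hi_q = 0.5, loq = NULL) {
  m <- as_data_matrix(matrix)
  lo_policy <- match.arg(lo_policy)
  hi_policy <- match.arg(hi_policy)
  p <- ncol(m$values)
  lo <- rep(-Inf, p); hi <- rep(Inf, p)
  miss <- which(colSums(m$mask) > 0)
  for (j in miss) {
    obs <- m$values[!m$mask[, j], j]
    hi[j] <- switch(hi_policy,
      min_observed = min(obs),
      quantile = unname(stats::quantile(obs, hi_q, type = 7)),
      fixed_loq = {
        if (is.null(loq) || length(loq) != p)
          stop("hi_policy = 'fixed_loq' needs a length-p `loq` vector",
               call. = FALSE)
        loq[j]
      })
    lo[j] <- if (lo_policy == "zero") 0 else -Inf
    if (lo[j] >= hi[j])
      stop(sprintf("variable %s: lower bound %.3g >= upper bound %.3g",
                   m$col_ids[j], lo[j], hi[j]), call. = FALSE)
  }
  list(lo = lo, hi = hi)
}

# Deterministic substream seed for (seed, outer pass, variable index).
# Keeps every per-variable update reproducible independently of the worker
# count and of execution order.  Constants are distinct large primes; the
# result stays inside the 32-bit integer range set.seed() accepts.
substream_seed <- function(seed, outer, j) {
  s <- (as.double(seed %% 1000003L) * 2654435761 +
        as.double(outer) * 40503 + as.double(j) * 97) %% 2147483647
  as.integer(s) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
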