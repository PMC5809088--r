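## Gibbs-sampler imputation with an embedded elastic-net prediction model.
## Each missing variable is repeatedly re-drawn from a truncated normal
## centred on the elastic-net prediction from all other variables, with the
## RMSD of the missing part as the sampling SD and the variable's detection
## limit as the upper truncation point.

#' Initialize missing values before Gibbs sampling
#'
#' @param matrix A [data_matrix()] with missing cells.
#' @param method `"qrilc"` (draws below each variable's observed minimum)
#'   or `"half_min"` (deterministic half-minimum fill).
#' @param seed Optional integer seed (used by QRILC draws).
#' @return A complete [data_matrix()]; observed cells unchanged.
#' @export
initialize_missing <- function(matrix, method = c("qrilc", "half_min"),
                               seed = NULL) {
  m <- as_data_matrix(matrix)
  method <- match.arg(method)
  if (n_missing(m) == 0) return(m)
  check_min_observed(m, 3L, "initialization")
  switch(method,
         qrilc = impute_qrilc(m, seed = seed),
         half_min = impute_hm(m))
}

#' Order missing variables for sequential imputation
#'
#' Variables are imputed from the least missing to the most, so that
#' better-observed variables stabilize first and inform the harder ones.
#'
#' @param matrix A [data_matrix()].
#' @return Integer vector of column indices with at least one missing
#'   cell, sorted by ascending missing count (ties by column index).
#' @export
order_missing_variables <- function(matrix) {
  m <- as_data_matrix(matrix)
  cnt <- colSums(m$mask)
  idx <- unname(which(cnt > 0))
  idx[order(cnt[idx], idx)]
}

#' Elastic-net fit-and-predict
#'
#' Fits y ~ X with the elastic-net penalty
#' lambda * \[(1 - alpha)/2 ||beta||_2^2 + alpha ||beta||_1\] on the
#' 1/(2n)-averaged squared-error objective (glmnet's parameterization),
#' predictors standardized internally and an unpenalized intercept, and
#' returns fitted values on the original scale.  `lambda = 0` is ordinary
#' least squares.
#'
#' @param y Complete numeric response of length n.
#' @param X Complete numeric predictor matrix (n x q).
#' @param lambda Nonnegative penalty weight.
#' @param alpha Mixing parameter in \[0, 1\].
#' @return Numeric vector of n fitted values.
#' @export
fit_predict_elastic_net <- function(y, X, lambda = 0.01, alpha = 0.5) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X)) stop("y and X must be complete", call. = FALSE)
  n <- length(y)
  if (n < 3 || nrow(X) != n) stop("need n >= 3 rows in y and X", call. = FALSE)
  if (stats::sd(y) == 0) return(rep(y[1], n))
  if (lambda == 0) {
    fit <- stats::lm.fit(cbind(1, X), y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # rank-deficient: drop aliased columns
    return(drop(cbind(1, X) %*% beta))
  }
  if (ncol(X) < 2) X <- cbind(X, 0)  # glmnet needs >= 2 columns; a
                                     # zero-variance column gets coefficient 0
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = lambda, standardize = TRUE,
                        intercept = TRUE, thresh = 1e-9)
  # equivalent to predict(fit, X) without the S4 dispatch overhead,
  # which dominates when the fit is refit every Gibbs cycle
  as.numeric(fit$a0) + drop(X %*% fit$beta[, 1L])
}

#' Root mean square deviation over the missing part
#'
#' The Gibbs sampling SD: the RMSD between fitted values and the current
#' working values, restricted to the missing elements.
#'
#' @param y_hat,y_prime Numeric vectors of length n.
#' @param missing_index Indices of the missing elements (nonempty).
#' @return Nonnegative scalar sqrt(mean((y_hat - y_prime)^2)) over
#'   `missing_index`.
#' @export
rmsd_missing <- function(y_hat, y_prime, missing_index) {
  if (length(missing_index) == 0)
    stop("missing_index must be nonempty", call. = FALSE)
  r <- y_hat[missing_index] - y_prime[missing_index]
  sqrt(mean(r^2))
}

#' One block of Gibbs cycles for a single missing variable
#'
#' Runs `iters_each` cycles of predict / estimate / sample: fit the
#' elastic net of the working vector on all other variables, compute
#' fitted values and the missing-part RMSD sigma, then re-draw every
#' missing element from N(fitted, sigma^2) truncated to \[lo, hi\].
#' If sigma collapses to exactly zero the fitted values are clamped into
#' the bounds instead of sampled.
#'
#' @param state List with `y_prime` (working vector), `missing_index`,
#'   `lo`, `hi`.
#' @param X_other Complete matrix of all other variables (n x (p-1)).
#' @param iters_each Number of Gibbs cycles.
#' @param lambda,alpha Elastic-net hyperparameters.
#' @param trace_rows Row indices (within the variable) whose (y_hat,
#'   y_tilde, sigma) sequence should be recorded; empty for none.
#' @return List with the updated `state` and `trace`, a data frame with
#'   one row per (cycle, traced row).
#' @export
gibbs_update_variable <- function(state, X_other, iters_each,
                                  lambda = 0.01, alpha = 0.5,
                                  trace_rows = integer(0)) {
  y <- state$y_prime
  mi <- state$missing_index
  lo <- state$lo; hi <- state$hi
  if (!(lo < hi)) stop("requires lo < hi", call. = FALSE)
  keep <- length(trace_rows) > 0
  tr <- if (keep)
    data.frame(cycle = integer(0), row = integer(0),
               y_hat = numeric(0), y_tilde = numeric(0), sigma = numeric(0))
  else NULL
  for (it in seq_len(iters_each)) {
    y_hat <- fit_predict_elastic_net(y, X_other, lambda, alpha)
    sigma <- rmsd_missing(y_hat, y, mi)
    if (sigma == 0) {
      warning("sigma collapsed to 0; clamping fitted values into bounds",
              call. = FALSE)
      y_new <- pmin(pmax(y_hat[mi], lo), hi)
    } else {
      y_new <- sample_truncated_normal(length(mi), mu = y_hat[mi],
                                       sigma = sigma, lo = lo, hi = hi)
    }
    y[mi] <- y_new
    if (keep) {
      pos <- match(trace_rows, mi)
      tr <- rbind(tr, data.frame(cycle = it, row = trace_rows,
                                 y_hat = y_hat[trace_rows],
                                 y_tilde = y[trace_rows],
                                 sigma = sigma))
    }
  }
  state$y_prime <- y
  state$y_hat <- y_hat
  state$sigma <- sigma
  list(state = state, trace = tr)
}

#' Gibbs-sampler imputation of left-censored missing values
#'
#' The main imputation routine.  After initialization, missing variables
#' are visited in order of ascending missing count; each visit runs
#' `iters_each` Gibbs cycles ([gibbs_update_variable()]) of elastic-net
#' prediction and truncated-normal sampling, and the whole matrix is
#' swept `iters_all` times.  The final draw is the imputed value.
#'
#' With `workers = 1` each variable's update sees the latest values of all
#' others (sequential Gibbs).  With `workers > 1`, within each outer pass
#' all variables are updated against a frozen snapshot of the matrix from
#' the start of the pass and committed together; per-variable RNG
#' substreams make the result identical for any `workers > 1`.
#'
#' @param matrix A [data_matrix()] (or plain matrix with `NA`s).
#' @param bounds Optional list with vectors `lo`, `hi` of length p; by
#'   default built by [truncation_bounds()] under the config's policies.
#' @param config A [run_config()].
#' @param trace_cells Optional 2-column matrix (row, col) of cells whose
#'   Gibbs chains should be recorded.
#' @return An object of class `imputation_result`: list with `matrix`
#'   (complete [data_matrix()]), `method`, `config`, `traces` (long data
#'   frame: cycle, row, col, y_hat, y_tilde, sigma), `cycles_per_variable`,
#'   and `seed`.
#' @examples
#' set.seed(7)
#' sim <- simulate_two_group_dataset(n_per_group = 15, covariance = diag(6))
#' cen <- generate_mnar_mask(sim$data, mnar_spec(0.5, 0.3, 0.6), seed = 7)
#' res <- impute_gsimp(cen$censored,
#'                     config = run_config(iters_each = 5, iters_all = 2))
#' res$matrix
#' @export
impute_gsimp <- function(matrix, bounds = NULL, config = run_config(),
                         trace_cells = NULL) {
  m <- as_data_matrix(matrix)
  if (n_missing(m) == 0) {
    warning("no missing cells; returning input unchanged", call. = FALSE)
    return(structure(list(matrix = m, method = "gsimp", config = config,
                          traces = NULL, cycles_per_variable = 0L,
                          seed = config$seed),
                     class = "imputation_result"))
  }
  check_min_observed(m, 3L, "gsimp")
  if (is.null(bounds))
    bounds <- truncation_bounds(m, config$lo_policy, config$hi_policy,
                                config$hi_q, config$loq)
  if (length(bounds$lo) != ncol(m$values) || length(bounds$hi) != ncol(m$values))
    stop("bounds must have length p", call. = FALSE)

  init <- initialize_missing(m, config$initialization,
                             seed = substream_seed(config$seed, 0L, 0L))
  vals <- init$values
  K <- order_missing_variables(m)
  trace_list <- list()
  if (!is.null(trace_cells)) {
    trace_cells <- base::matrix(as.integer(trace_cells), ncol = 2)
    if (any(!m$mask[trace_cells]))
      stop("trace_cells must index missing cells", call. = FALSE)
  }

  update_one <- function(j, snapshot, outer) {
    mi <- which(m$mask[, j])
    state <- list(y_prime = snapshot[, j], missing_index = mi,
                  lo = bounds$lo[j], hi = bounds$hi[j])
    tr_rows <- if (is.null(trace_cells)) integer(0) else
      trace_cells[trace_cells[, 2] == j, 1]
    set.seed(substream_seed(config$seed, outer, j))
    out <- gibbs_update_variable(state, snapshot[, -j, drop = FALSE],
                                 config$iters_each, config$lambda,
                                 config$alpha, trace_rows = tr_rows)
    if (!is.null(out$trace) && nrow(out$trace)) {
      out$trace$col <- j
      out$trace$cycle <- out$trace$cycle + (outer - 1L) * config$iters_each
    }
    out
  }

  for (outer in seq_len(config$iters_all)) {
    if (config$workers > 1L) {
      snapshot <- vals
      outs <- parallel::mclapply(K, update_one, snapshot = snapshot,
                                 outer = outer,
                                 mc.cores = min(config$workers, length(K)))
      for (i in seq_along(K)) {
        vals[, K[i]] <- outs[[i]]$state$y_prime
        if (!is.null(outs[[i]]$trace)) trace_list[[length(trace_list) + 1L]] <-
            outs[[i]]$trace
      }
    } else {
      for (j in K) {
        out <- update_one(j, vals, outer)
        vals[, j] <- out$state$y_prime
        if (!is.null(out$trace)) trace_list[[length(trace_list) + 1L]] <-
            out$trace
      }
    }
  }
  traces <- if (length(trace_list)) {
    tr <- do.call(rbind, trace_list)
    tr <- tr[order(tr$col, tr$row, tr$cycle), c("cycle", "row", "col",
                                                "y_hat", "y_tilde", "sigma")]
    rownames(tr) <- NULL
    tr
  } else NULL
  structure(list(
    matrix = data_matrix(vals, m$row_ids, m$col_ids),
    method = "gsimp", config = config, traces = traces,
    cycles_per_variable = config$iters_each * config$iters_all,
    seed = config$seed
  ), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method=%s, %d x %d matrix, %d Gibbs cycles per missing variable, seed=%d\n",
              x$method, nrow(x$matrix$values), ncol(x$matrix$values),
              x$cycles_per_variable, x$seed))
  invisible(x)
}

#' Impute by a named method
#'
#' Dispatch helper used by the command line and the evaluation pipeline.
#'
#' @param matrix A [data_matrix()].
#' @param method One of `"gsimp"`, `"qrilc"`, `"hm"`, `"knn-tn"`.
#' @param config A [run_config()].
#' @param ... Passed to the method (e.g. `bounds`, `trace_cells`).
#' @return An `imputation_result`.
#' @export
impute_method <- function(matrix, method, config = run_config(), ...) {
  m <- as_data_matrix(matrix)
  method <- match.arg(method, c("gsimp", "qrilc", "hm", "knn-tn"))
  if (method == "gsimp") return(impute_gsimp(m, config = config, ...))
  completed <- switch(method,
    qrilc = impute_qrilc(m, tune_sigma = config$tune_sigma,
                         seed = config$seed),
    hm = impute_hm(m),
    `knn-tn` = impute_knn_tn(m, k = config$k))
  structure(list(matrix = completed, method = method, config = config,
                 traces = NULL, cycles_per_variable = 0L,
                 seed = config$seed),
            class = "imputation_result")
}
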