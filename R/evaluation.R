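## Benchmark metrics for imputation quality: per-variable NRMSE and its
## rank sum, ordination (PCA/PLS) Procrustes errors, correlation of
## t-test p-values, and the true positive rate of differential-variable
## detection.

#' Normalized root mean squared error
#'
#' RMSE between true and imputed values normalized by the SD of the true
#' values, computed over the masked cells of one variable.
#'
#' @param true_values,imputed_values Equal-length numeric vectors
#'   (length >= 2).
#' @return sqrt(mean((true - imputed)^2) / var(true)), with `var` using
#'   denominator n - 1.
#' @export
nrmse <- function(true_values, imputed_values) {
  if (length(true_values) != length(imputed_values) || length(true_values) < 2)
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  v <- stats::var(true_values)
  if (!is.finite(v) || v == 0)
    stop("true values have zero variance; NRMSE undefined", call. = FALSE)
  sqrt(mean((true_values - imputed_values)^2) / v)
}

#' Sum of NRMSE ranks across missing variables
#'
#' Within each missing variable, methods are ranked ascending by NRMSE
#' (rank 1 = most accurate, ties get average ranks); ranks are summed per
#' method.  Lower is better; a method that wins every variable scores k.
#'
#' @param nrmse_table k x m numeric matrix: one row per missing variable,
#'   one column per method.
#' @return Named numeric vector of per-method rank sums.
#' @export
sum_of_ranks <- function(nrmse_table) {
  nrmse_table <- as.matrix(nrmse_table)
  if (any(!is.finite(nrmse_table)))
    stop("NRMSE table contains non-finite entries", call. = FALSE)
  if (ncol(nrmse_table) < 2) stop("need at least 2 methods", call. = FALSE)
  ranks <- t(apply(nrmse_table, 1, rank))
  if (nrow(nrmse_table) == 1L) ranks <- matrix(ranks, nrow = 1)
  out <- colSums(ranks)
  names(out) <- colnames(nrmse_table)
  out
}

#' Ordination scores by PCA or two-class PLS
#'
#' @param matrix A complete [data_matrix()] (or numeric matrix).
#' @param labels Binary group labels (required for `mode = "pls"`).
#' @param mode `"pca"` (unsupervised) or `"pls"` (supervised).
#' @param n_components Number of axes/latent variables.
#' @return n x n_components score matrix (PCA scores of the
#'   column-centred data, or PLS X-scores with labels encoded 0/1).
#' @export
ordination_scores <- function(matrix, labels = NULL,
                              mode = c("pca", "pls"), n_components = 2) {
  m <- as_data_matrix(matrix)
  mode <- match.arg(mode)
  if (n_missing(m) > 0) stop("matrix must be complete", call. = FALSE)
  vals <- m$values
  if (n_components > min(nrow(vals) - 1, ncol(vals)))
    stop("n_components exceeds min(n - 1, p)", call. = FALSE)
  if (mode == "pca") {
    sc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)$x
    return(sc[, seq_len(n_components), drop = FALSE])
  }
  if (is.null(labels)) stop("PLS requires group labels", call. = FALSE)
  y <- as.numeric(as.factor(labels)) - 1
  if (length(unique(y)) != 2) stop("PLS requires exactly 2 groups", call. = FALSE)
  fit <- mixOmics::pls(X = vals, Y = y, ncomp = n_components, scale = FALSE)
  unname(as.matrix(fit$variates$X))
}

#' Procrustes sum of squared errors between two ordinations
#'
#' Classical Procrustes superimposition: the target configuration is
#' translated, rotated/reflected, and isotropically scaled to best match
#' the fixed reference, and the residual sum of squares is returned
#' (vegan's convention with scaling enabled).  Zero means the two
#' ordinations differ only by a similarity transform.
#'
#' @param reference_scores,target_scores n x c score matrices.
#' @return Nonnegative residual sum of squares.
#' @export
procrustes_sse <- function(reference_scores, target_scores) {
  X <- as.matrix(reference_scores); Y <- as.matrix(target_scores)
  if (!all(dim(X) == dim(Y))) stop("score matrices must match in shape",
                                   call. = FALSE)
  if (all(abs(sweep(Y, 2, colMeans(Y))) < 1e-300) ||
      all(abs(sweep(X, 2, colMeans(X))) < 1e-300))
    stop("degenerate (all-coincident) configuration", call. = FALSE)
  pr <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
  unname(pr$ss)
}

welch_or_student_p <- function(x, g, pooled = FALSE) {
  stats::t.test(x ~ g, var.equal = pooled)$p.value
}

#' Correlation of log-transformed t-test p-values
#'
#' For each missing variable, two-sample t-tests compare the groups on
#' the original and the imputed data; the Pearson correlation of the
#' natural-log p-value vectors measures how well imputation preserves the
#' univariate statistics.
#'
#' @param original,imputed Complete [data_matrix()] objects of the same
#'   shape.
#' @param labels Binary group labels (each group >= 2 observations).
#' @param missing_variables Column indices of the variables that were
#'   imputed (at least 3).
#' @param pooled Use the pooled-variance (classic Student) t-test instead
#'   of Welch's.
#' @return Pearson correlation in \[-1, 1\].
#' @export
pvalue_log_correlation <- function(original, imputed, labels,
                                   missing_variables, pooled = FALSE) {
  o <- as_data_matrix(original); im <- as_data_matrix(imputed)
  if (length(missing_variables) < 3)
    stop("need at least 3 missing variables", call. = FALSE)
  g <- as.factor(labels)
  if (nlevels(g) != 2 || any(table(g) < 2))
    stop("need two groups with at least 2 observations each", call. = FALSE)
  p_o <- vapply(missing_variables,
                function(j) welch_or_student_p(o$values[, j], g, pooled),
                numeric(1))
  p_i <- vapply(missing_variables,
                function(j) welch_or_student_p(im$values[, j], g, pooled),
                numeric(1))
  stats::cor(log(p_o), log(p_i))
}

#' True positive rate of differential-variable detection after imputation
#'
#' S is the set of variables significant on the original data at the
#' cutoff, S' the set significant on the imputed data; the TPR is
#' |S intersect S'| / |S|.
#'
#' @param p_original,p_imputed Equal-length p-value vectors.
#' @param cutoff Significance level.
#' @return TPR in \[0, 1\].
#' @export
true_positive_rate <- function(p_original, p_imputed, cutoff = 0.05) {
  if (length(p_original) != length(p_imputed))
    stop("p-value vectors must have equal length", call. = FALSE)
  S <- which(p_original < cutoff)
  if (length(S) == 0)
    stop("no variable significant on the original data; TPR undefined",
         call. = FALSE)
  Sp <- which(p_imputed < cutoff)
  length(intersect(S, Sp)) / length(S)
}

#' Run the full imputation benchmark
#'
#' Applies each method to the censored matrix and assembles all metrics:
#' per-variable NRMSE on the masked cells, SOR, PCA- (and, with labels,
#' PLS-) Procrustes error of the imputed ordination against the original
#' one, correlation of log t-test p-values over the missing variables,
#' and TPR at each cutoff.
#'
#' @param original Complete [data_matrix()] with the true values.
#' @param censored The same matrix with an MNAR mask applied.
#' @param labels Optional binary group labels; enables the labeled
#'   metrics (PLS-Procrustes, p-value correlation, TPR).
#' @param methods Character vector of method names (see
#'   [impute_method()]).
#' @param config A [run_config()]; `config$seed` seeds every method.
#' @param cutoffs Significance cutoffs for the TPR.
#' @param n_components Ordination components for the Procrustes
#'   comparison.
#' @param pooled Use pooled-variance t-tests.
#' @return An object of class `evaluation_report`: list with `nrmse`
#'   (k x m matrix), `sor`, `procrustes` (data frame), `p_correlation`,
#'   `tpr` (methods x cutoffs), `missing_vars`, `errors` (per-method
#'   failure messages, if any).
#' @export
evaluate_methods <- function(original, censored, labels = NULL,
                             methods = c("gsimp", "qrilc", "hm", "knn-tn"),
                             config = run_config(), cutoffs = c(0.05, 0.01),
                             n_components = 2, pooled = FALSE) {
  o <- as_data_matrix(original)
  cen <- as_data_matrix(censored)
  if (!all(dim(o) == dim(cen)))
    stop("original and censored matrices must have the same shape",
         call. = FALSE)
  if (n_missing(o) > 0) stop("original matrix must be complete", call. = FALSE)
  miss_vars <- which(colSums(cen$mask) > 0)
  if (length(miss_vars) == 0) stop("censored matrix has no missing cells",
                                   call. = FALSE)
  completed <- list(); errors <- list()
  for (meth in methods) {
    res <- tryCatch(impute_method(cen, meth, config),
                    error = function(e) e)
    if (inherits(res, "error")) errors[[meth]] <- conditionMessage(res)
    else completed[[meth]] <- res$matrix
  }
  ok <- names(completed)
  if (length(ok) == 0) stop("every method failed", call. = FALSE)

  nr <- sapply(completed, function(imp)
    vapply(miss_vars, function(j) {
      idx <- cen$mask[, j]
      nrmse(o$values[idx, j], imp$values[idx, j])
    }, numeric(1)))
  nr <- matrix(nr, nrow = length(miss_vars),
               dimnames = list(o$col_ids[miss_vars], ok))
  sor <- if (length(ok) >= 2) sum_of_ranks(nr) else NULL

  ref_pca <- ordination_scores(o, mode = "pca", n_components = n_components)
  pca_sse <- vapply(completed, function(imp)
    procrustes_sse(ref_pca, ordination_scores(imp, mode = "pca",
                                              n_components = n_components)),
    numeric(1))
  procr <- data.frame(method = ok, pca_sse = unname(pca_sse),
                      pls_sse = NA_real_)
  p_cor <- NULL; tpr <- NULL
  if (!is.null(labels)) {
    ref_pls <- ordination_scores(o, labels, "pls", n_components)
    procr$pls_sse <- vapply(completed, function(imp)
      procrustes_sse(ref_pls, ordination_scores(imp, labels, "pls",
                                                n_components)),
      numeric(1))
    g <- as.factor(labels)
    p_o <- vapply(miss_vars,
                  function(j) welch_or_student_p(o$values[, j], g, pooled),
                  numeric(1))
    p_imp <- sapply(completed, function(imp)
      vapply(miss_vars,
             function(j) welch_or_student_p(imp$values[, j], g, pooled),
             numeric(1)))
    p_imp <- matrix(p_imp, nrow = length(miss_vars), dimnames = list(NULL, ok))
    p_cor <- if (length(miss_vars) >= 3)
      apply(p_imp, 2, function(pi) stats::cor(log(p_o), log(pi)))
    else NULL
    if (any(p_o < max(cutoffs))) {
      tpr <- sapply(cutoffs, function(ct) {
        if (!any(p_o < ct)) return(rep(NA_real_, length(ok)))
        apply(p_imp, 2, function(pi) true_positive_rate(p_o, pi, ct))
      })
      tpr <- matrix(tpr, nrow = length(ok),
                    dimnames = list(ok, paste0("p<", cutoffs)))
    }
  }
  structure(list(nrmse = nr, sor = sor, procrustes = procr,
                 p_correlation = p_cor, tpr = tpr,
                 missing_vars = miss_vars,
                 errors = if (length(errors)) errors else NULL),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", nrow(x$nrmse), "missing variables,",
      ncol(x$nrmse), "methods\n")
  if (!is.null(x$sor)) {
    cat("sum of NRMSE ranks (lower = better):\n")
    print(round(x$sor, 1))
  }
  cat("median NRMSE per method:\n")
  print(round(apply(x$nrmse, 2, stats::median), 4))
  if (!is.null(x$p_correlation)) {
    cat("log p-value correlation:\n"); print(round(x$p_correlation, 4))
  }
  if (!is.null(x$errors))
    cat("failed methods:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
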