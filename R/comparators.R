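## Reference left-censored imputers used for benchmarking: half-minimum
## substitution, QRILC, and truncated-normal kNN.

#' Half-minimum substitution
#'
#' Replaces every missing cell of a variable with half of the minimum of
#' its observed values — the simplest detection-limit substitution rule
#' still common in metabolomics pipelines.
#'
#' @param matrix A [data_matrix()] (or plain matrix with `NA`s).
#' @return A complete [data_matrix()]; observed cells unchanged.
#' @export
impute_hm <- function(matrix) {
  m <- as_data_matrix(matrix)
  fully_missing <- which(colSums(m$mask) == nrow(m$values))
  if (length(fully_missing))
    stop("fully missing variable(s): ",
         paste(m$col_ids[fully_missing], collapse = ", "), call. = FALSE)
  vals <- m$values
  for (j in which(colSums(m$mask) > 0)) {
    vals[m$mask[, j], j] <- min(vals[!m$mask[, j], j]) / 2
  }
  data_matrix(vals, m$row_ids, m$col_ids)
}

#' QRILC: quantile-regression imputation of left-censored data
#'
#' For each missing variable, estimates the mean and SD of the underlying
#' complete normal from the observed upper tail
#' ([censored_quantile_estimate()]) and draws every missing element from
#' that normal truncated above at the variable's observed minimum.
#'
#' @param matrix A [data_matrix()].
#' @param tune_sigma Multiplier applied to the estimated SD before
#'   sampling (1 = use the estimate as is).
#' @param seed Optional integer seed.
#' @return A complete [data_matrix()]; all imputed cells lie below the
#'   observed minimum of their variable.
#' @export
impute_qrilc <- function(matrix, tune_sigma = 1, seed = NULL) {
  m <- as_data_matrix(matrix)
  check_min_observed(m, 3L, "QRILC")
  if (!is.null(seed)) set.seed(seed)
  vals <- m$values
  n <- nrow(vals)
  for (j in which(colSums(m$mask) > 0)) {
    obs <- vals[!m$mask[, j], j]
    mj <- sum(m$mask[, j])
    est <- tryCatch(
      censored_quantile_estimate(obs, missing_fraction = mj / n),
      error = function(e) stop(sprintf("QRILC failed on variable %s: %s",
                                       m$col_ids[j], conditionMessage(e)),
                               call. = FALSE))
    vals[m$mask[, j], j] <- sample_truncated_normal(
      mj, mu = est$mu, sigma = tune_sigma * est$sigma,
      lo = -Inf, hi = min(obs))
  }
  data_matrix(vals, m$row_ids, m$col_ids)
}

#' kNN-TN: correlation-based k-nearest-neighbour imputation on
#' truncated-normal standardized data
#'
#' Each missing variable's mean and SD are estimated by truncated-normal
#' maximum likelihood ([truncnorm_mle()]) treating the observed minimum as
#' the censoring point (observed values are truncated below at it);
#' complete variables use their sample moments.  After standardizing by
#' these estimates, each missing cell is imputed as the
#' |Pearson r|-weighted average of the cell's row values in the k
#' variables most correlated with the target among those observed in that
#' row, and de-standardized.  No truncation is applied, so imputed values
#' can exceed the censoring point — the characteristic weakness of this
#' approach on strongly censored data.
#'
#' @param matrix A [data_matrix()].
#' @param k Number of neighbour variables.
#' @return A complete [data_matrix()].
#' @export
impute_knn_tn <- function(matrix, k = 10L) {
  m <- as_data_matrix(matrix)
  vals <- m$values
  n <- nrow(vals); p <- ncol(vals)
  if (p < 2) stop("kNN-TN needs at least 2 variables", call. = FALSE)
  k <- min(as.integer(k), p - 1L)
  check_min_observed(m, 10L, "kNN-TN")
  mu <- numeric(p); sg <- numeric(p)
  for (j in seq_len(p)) {
    obs <- vals[!m$mask[, j], j]
    if (any(m$mask[, j])) {
      est <- tryCatch(truncnorm_mle(obs, lo = min(obs), hi = Inf),
                      error = function(e) NULL)
      if (is.null(est)) {
        # heavily censored small samples can have no interior MLE
        # (likelihood increases as mu -> -Inf); use observed moments
        warning(sprintf("variable %s: truncated-normal MLE diverged; using sample moments",
                        m$col_ids[j]), call. = FALSE)
        est <- list(mu = mean(obs), sigma = sqrt(mean((obs - mean(obs))^2)))
      }
      mu[j] <- est$mu; sg[j] <- est$sigma
    } else {
      mu[j] <- mean(obs); sg[j] <- sqrt(mean((obs - mu[j])^2))
    }
    if (sg[j] <= 0) stop(sprintf("variable %s has zero scale", m$col_ids[j]),
                         call. = FALSE)
  }
  z <- sweep(sweep(vals, 2, mu), 2, sg, "/")
  cors <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  cors[!is.finite(cors)] <- 0
  diag(cors) <- 0
  for (j in which(colSums(m$mask) > 0)) {
    ord <- order(-abs(cors[, j]), seq_len(p))  # ties by variable index
    for (i in which(m$mask[, j])) {
      usable <- ord[!m$mask[i, ord] & abs(cors[ord, j]) > 0]
      nb <- usable[seq_len(min(k, length(usable)))]
      if (length(nb) == 0) {
        z[i, j] <- 0  # no usable neighbour: fall back to the variable mean
      } else {
        w <- abs(cors[nb, j])
        z[i, j] <- sum(w * z[i, nb]) / sum(w)
      }
    }
  }
  out <- sweep(sweep(z, 2, sg, "*"), 2, mu, "+")
  out[!m$mask] <- vals[!m$mask]  # conserve observed cells bitwise
  data_matrix(out, m$row_ids, m$col_ids)
}
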