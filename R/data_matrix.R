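#' Construct a data matrix with an explicit missingness mask
#'
#' The basic container used throughout the package: a numeric
#' samples-by-variables abundance matrix together with a logical mask
#' marking missing cells.  Rows are observations (samples), columns are
#' variables (metabolites); this is the usual orientation of a quantified
#' metabolomics table.
#'
#' @param values Numeric matrix (n observations x p variables).  Missing
#'   cells are `NA`.
#' @param row_ids,col_ids Optional character vectors of observation and
#'   variable labels; default to the dimnames of `values` or generated
#'   labels.
#' @return An object of class `data_matrix`: a list with elements
#'   `values` (numeric matrix, `NA` at masked cells), `mask` (logical
#'   matrix, `TRUE` = missing), `row_ids`, `col_ids`.
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 5, 6), nrow = 3)
#' dm <- data_matrix(m)
#' n_missing(dm)
#' @export
data_matrix <- function(values, row_ids = NULL, col_ids = NULL) {
  if (!is.matrix(values) || !(is.numeric(values) || is.logical(values)))
    stop("`values` must be a numeric matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(row_ids))
    row_ids <- rownames(values) %||% paste0("obs_", seq_len(nrow(values)))
  if (is.null(col_ids))
    col_ids <- colnames(values) %||% paste0("var_", seq_len(ncol(values)))
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values))
    stop("id lengths must match matrix dimensions", call. = FALSE)
  mask <- !is.finite(values)
  values[mask] <- NA_real_
  dimnames(values) <- list(row_ids, col_ids)
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask,
         row_ids = as.character(row_ids), col_ids = as.character(col_ids)),
    class = "data_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d observations x %d variables, %d missing cells (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' @export
as.matrix.data_matrix <- function(x, ...) x$values

#' Number of missing cells in a data matrix
#' @param x A `data_matrix`.
#' @return Integer count of masked cells.
#' @export
n_missing <- function(x) {
  stopifnot(inherits(x, "data_matrix"))
  sum(x$mask)
}

#' Per-variable missing counts
#' @param x A `data_matrix`.
#' @return Integer vector of length p, named by variable.
#' @export
missing_per_variable <- function(x) {
  stopifnot(inherits(x, "data_matrix"))
  colSums(x$mask)
}

as_data_matrix <- function(x) {
  if (inherits(x, "data_matrix")) x else data_matrix(as.matrix(x))
}

check_min_observed <- function(x, min_obs, what = "imputation") {
  obs <- nrow(x$values) - missing_per_variable(x)
  miss_cols <- which(colSums(x$mask) > 0)
  bad <- miss_cols[obs[miss_cols] < min_obs]
  if (length(bad))
    stop(sprintf("%s requires >= %d observed values per missing variable; violated by: %s",
                 what, min_obs, paste(x$col_ids[bad], collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a samples-by-variables matrix from CSV
#'
#' Expects a header row of variable names and a first column of
#' observation IDs.  Cells matching one of `na_tokens` (or empty cells)
#' are flagged missing.
#'
#' @param path Path to a CSV file.
#' @param na_tokens Character vector of tokens treated as missing.
#' @param transpose If `TRUE` the file stores variables in rows and is
#'   transposed after reading.
#' @return A [data_matrix()].
#' @export
read_matrix <- function(path, na_tokens = c("NA", "NaN", ""), transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged CSV: rows have differing field counts (%s)",
                 paste(unique(nf), collapse = ", ")), call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
  if (ncol(raw) < 2L) stop("CSV must have an ID column plus data columns", call. = FALSE)
  row_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- matrix(NA_real_, nrow(cells), ncol(cells))
  is_na <- matrix(trimws(cells) %in% na_tokens, nrow(cells), ncol(cells))
  suppressWarnings(num <- as.numeric(cells))
  bad <- which(!is_na & is.na(matrix(num, nrow(cells))), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("cell at row '%s', column '%s' is not numeric: \"%s\"",
                 row_ids[bad[1, 1]], colnames(cells)[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  vals[!is_na] <- num[!is_na]
  dimnames(vals) <- list(row_ids, colnames(cells))
  if (transpose) vals <- t(vals)
  data_matrix(vals)
}

#' Write a data matrix to CSV
#'
#' Missing cells are written as `"NA"` so that
#' `read_matrix(write_matrix(m))` round-trips both values and mask.
#'
#' @param matrix A [data_matrix()] (or plain numeric matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path) {
  m <- as_data_matrix(matrix)
  df <- data.frame(id = m$row_ids, m$values, check.names = FALSE)
  names(df)[1] <- ""
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE),
    error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  invisible(path)
}
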