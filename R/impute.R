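# Chained-equations imputation.
#
# Fully numeric matrices only (categorical columns are assumed already
# one-hot encoded).  Missing cells are initialized at the fitting-split
# column mean and then refined over n_cycles sweeps; in each sweep every
# incomplete column is regressed on all other columns over the fitting rows
# with observed values, and its missing cells (in all rows) are replaced by
# the regression prediction.  Binary indicator columns use a logistic
# regression and are imputed with the predicted class probability; other
# columns use a linear fit.  Observed cells are never altered, and no
# regression ever sees a held-out row.

# Rank-deficiency-safe linear coefficients (aliased columns get 0).
safe_lm_coef <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

safe_glm_coef <- function(X, y) {
  cf <- tryCatch(
    suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                     family = stats::binomial())$coefficients
    ),
    error = function(e) NULL
  )
  if (is.null(cf) || any(!is.finite(cf[!is.na(cf)]))) return(NULL)
  cf[is.na(cf)] <- 0
  cf
}

#' Impute missing values by chained equations
#'
#' Iterated column-wise regression imputation (a single completed dataset,
#' not multiple imputations). Columns are visited in ascending order of
#' missingness within each cycle; ties are broken by a seeded shuffle.
#' When \code{fit_rows} is given, all regressions are fitted on those rows
#' only and merely applied to the remaining rows, so held-out data never
#' influences the imputation model.
#'
#' @param mat numeric matrix with \code{NA}s.
#' @param n_cycles number of sweeps (>= 1); default 10.
#' @param seed integer seed for tie-breaking.
#' @param fit_rows indices of the rows regressions may be fitted on;
#'   default all rows.
#' @return completed matrix with attribute \code{impute_info}
#'   (columns imputed, cycles, fit rows).
#' @export
impute_chained <- function(mat, n_cycles = 10L, seed = 1L, fit_rows = NULL) {
  mat <- as.matrix(mat)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(mat))
  miss <- is.na(mat)
  if (!any(miss)) {
    attr(mat, "impute_info") <- list(columns = integer(0), n_cycles = n_cycles,
                                     fit_rows = fit_rows)
    return(mat)
  }

  n_miss_fit <- colSums(miss[fit_rows, , drop = FALSE])
  fully_missing <- which(n_miss_fit == length(fit_rows))
  if (length(fully_missing)) {
    stop("column(s) fully missing on the fitting rows: ",
         paste(colnames(mat)[fully_missing] %||% fully_missing, collapse = ", "),
         call. = FALSE)
  }

  # Initialize at fitting-split column means.
  col_mean <- colMeans(mat[fit_rows, , drop = FALSE], na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) mat[miss[, j], j] <- col_mean[j]

  todo <- which(colSums(miss) > 0)
  ord <- with_seed(seed, {
    jitter <- stats::runif(length(todo))
    todo[order(colSums(miss)[todo], jitter)]
  })

  is_binary <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[fit_rows, j][!miss[fit_rows, j]]
    all(v %in% c(0, 1)) && length(unique(v)) == 2L
  }, logical(1))

  for (cycle in seq_len(n_cycles)) {
    for (j in ord) {
      obs_fit <- fit_rows[!miss[fit_rows, j]]
      X_fit <- mat[obs_fit, -j, drop = FALSE]
      y_fit <- mat[obs_fit, j]
      rows_to_fill <- which(miss[, j])
      Xp <- cbind(1, mat[rows_to_fill, -j, drop = FALSE])
      if (is_binary[j]) {
        cf <- safe_glm_coef(X_fit, y_fit)
        if (!is.null(cf)) {
          mat[rows_to_fill, j] <- stats::plogis(drop(Xp %*% cf))
          next
        }
      }
      cf <- safe_lm_coef(X_fit, y_fit)
      mat[rows_to_fill, j] <- drop(Xp %*% cf)
    }
  }
  attr(mat, "impute_info") <- list(columns = todo, n_cycles = n_cycles,
                                   fit_rows = fit_rows)
  mat
}
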