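#' Build model-ready design matrices from a cohort table
#'
#' Applies the clinical preprocessing pipeline in the fixed order
#' one-hot encode, ICV scaling, normalization, chained-equations
#' imputation, and z-scores the radiomics block. Every statistic (one-hot
#' level sets, means, SDs, maxima, imputation regressions) is fitted on the
#' rows in \code{fit_ids} only and applied unchanged to the remaining
#' rows, so a held-out fold never leaks into the fitted statistics. The
#' provenance of every fitted statistic is recorded and can be audited
#' against the evaluation rows.
#'
#' @param table a cohort table (see [generate_cohort()] / [read_cohort()]).
#' @param schema a [feature_schema()] covering every column of
#'   \code{table}.
#' @param fit_ids row indices of the fitting split; default all rows.
#' @param n_impute_cycles sweeps of the chained-equations imputer.
#' @param seed seed for imputation tie-breaking.
#' @return list of class \code{design_matrices}: \code{clinical} and
#'   \code{radiomics} matrices (all rows, no missing values),
#'   \code{stage}, \code{time}, \code{event}, \code{subject_id}, and
#'   \code{stats} (fitted statistics with \code{fit_ids} provenance).
#' @export
build_design_matrices <- function(table, schema, fit_ids = seq_len(nrow(table)),
                                  n_impute_cycles = 10L, seed = 1L) {
  unmapped <- setdiff(names(table), names(schema))
  if (length(unmapped)) {
    stop("schema does not map column(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  roles <- schema[names(schema) %in% names(table)]

  icv_col <- names(roles)[roles == "icv"]
  icv <- if (length(icv_col)) table[[icv_col]] else NULL
  ids <- if (any(roles == "id")) table[[names(roles)[roles == "id"][1]]] else seq_len(nrow(table))

  col_stats <- list()
  clin_parts <- list()
  for (nm in names(roles)) {
    role <- roles[[nm]]
    if (role == "categorical") {
      fitted <- encode_one_hot(table[[nm]][fit_ids], name = nm)
      enc <- encode_one_hot(table[[nm]], levels = attr(fitted, "levels"), name = nm)
      col_stats[[nm]] <- list(role = role, levels = attr(fitted, "levels"))
      clin_parts[[nm]] <- enc
    } else if (role %in% c("unbounded_numeric", "bounded_numeric", "volumetric")) {
      x <- table[[nm]]
      if (role == "volumetric") {
        if (is.null(icv)) stop("volumetric column '", nm, "' but no icv column", call. = FALSE)
        x <- scale_volumetrics_by_icv(x, icv, subject_id = ids)
      }
      method <- if (role == "bounded_numeric") "max" else "zscore"
      st <- attr(normalize_numeric(x[fit_ids], method, name = nm), "stats")
      out <- normalize_numeric(x, method, stats = st, name = nm)
      col_stats[[nm]] <- list(role = role, norm = st)
      clin_parts[[nm]] <- matrix(as.numeric(out), ncol = 1,
                                 dimnames = list(NULL, nm))
    }
  }
  clinical <- do.call(cbind, unname(clin_parts))

  if (anyNA(clinical)) {
    clinical <- impute_chained(clinical, n_cycles = n_impute_cycles,
                               seed = seed, fit_rows = fit_ids)
    imp_info <- attr(clinical, "impute_info")
    attr(clinical, "impute_info") <- NULL
  } else {
    imp_info <- list(columns = integer(0), fit_rows = fit_ids)
  }

  rad_cols <- names(roles)[roles == "radiomics"]
  radiomics <- NULL
  if (length(rad_cols)) {
    radiomics <- matrix(0, nrow(table), length(rad_cols),
                        dimnames = list(NULL, rad_cols))
    for (nm in rad_cols) {
      st <- attr(normalize_numeric(table[[nm]][fit_ids], "zscore", name = nm), "stats")
      radiomics[, nm] <- normalize_numeric(table[[nm]], "zscore", stats = st, name = nm)
      col_stats[[nm]] <- list(role = "radiomics", norm = st)
    }
  }

  stats <- structure(
    list(fit_ids = fit_ids, columns = col_stats, impute = imp_info),
    class = "preproc_stats"
  )
  structure(
    list(
      clinical = clinical,
      radiomics = radiomics,
      stage = as.integer(table[[names(roles)[roles == "stage"]]]),
      time = as.numeric(table[[names(roles)[roles == "time"]]]),
      event = as.integer(table[[names(roles)[roles == "event"]]]),
      subject_id = ids,
      stats = stats
    ),
    class = "design_matrices"
  )
}

#' Audit a design build for train/test leakage
#'
#' Checks that every fitted statistic of a [build_design_matrices()] result
#' was computed on fitting rows disjoint from the given held-out rows.
#'
#' @param design a \code{design_matrices} object.
#' @param holdout_ids row indices of the evaluation split.
#' @return \code{TRUE} invisibly; errors if any overlap is found.
#' @export
assert_no_leakage <- function(design, holdout_ids) {
  overlap <- intersect(design$stats$fit_ids, holdout_ids)
  if (length(overlap)) {
    stop("preprocessing statistics were fitted on held-out rows: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  imp_overlap <- intersect(design$stats$impute$fit_rows, holdout_ids)
  if (length(imp_overlap)) {
    stop("imputation regressions were fitted on held-out rows", call. = FALSE)
  }
  invisible(TRUE)
}
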