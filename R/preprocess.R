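#' Column-role schema for a cohort table
#'
#' Preprocessing is driven by a named character vector mapping column names
#' to roles. Recognized roles:
#' \describe{
#'   \item{id}{subject identifier (passed through).}
#'   \item{categorical}{one-hot encoded; levels fixed on the fitting split.}
#'   \item{unbounded_numeric}{z-score normalized.}
#'   \item{bounded_numeric}{divided by the fitting-split maximum.}
#'   \item{volumetric}{divided by the subject's intracranial volume, then
#'     z-score normalized.}
#'   \item{icv}{the intracranial volume column (divisor only).}
#'   \item{radiomics}{numeric radiomics feature, z-score normalized.}
#'   \item{stage, time, event}{labels, passed through unchanged.}
#'   \item{ignore}{dropped (e.g. hidden ground-truth columns).}
#' }
#' Whether a clinical column is bounded ("limited") or unbounded is data-
#' dictionary knowledge and must be declared, not inferred.
#'
#' @param roles named character vector of column roles.
#' @return validated schema (named character vector, class
#'   \code{feature_schema}).
#' @export
feature_schema <- function(roles) {
  valid <- c("id", "categorical", "unbounded_numeric", "bounded_numeric",
             "volumetric", "icv", "radiomics", "stage", "time", "event", "ignore")
  bad <- setdiff(unique(roles), valid)
  if (length(bad)) {
    stop("unknown schema roles: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(roles)) || any(!nzchar(names(roles)))) {
    stop("schema roles must be named by column", call. = FALSE)
  }
  for (r in c("stage", "time", "event")) {
    if (sum(roles == r) != 1L) stop("schema needs exactly one '", r, "' column", call. = FALSE)
  }
  if (any(roles == "volumetric") && sum(roles == "icv") != 1L) {
    stop("schema with volumetric columns needs exactly one 'icv' column", call. = FALSE)
  }
  structure(roles, class = "feature_schema")
}

#' Default schema for the synthetic cohort CSV dialect
#'
#' Maps the column naming convention of [generate_cohort()] /
#' [write_cohort()] to roles: \code{clin_num_*} unbounded, \code{clin_mmse}
#' bounded, \code{clin_vol_*} volumetric, \code{clin_cat_*} categorical,
#' \code{rad_*} radiomics, \code{latent_*} ignored.
#'
#' @param table a cohort table.
#' @return a [feature_schema()].
#' @export
default_schema <- function(table) {
  nm <- names(table)
  role <- rep("ignore", length(nm))
  role[nm == "subject_id"] <- "id"
  role[grepl("^clin_num_", nm)] <- "unbounded_numeric"
  role[nm == "clin_mmse"] <- "bounded_numeric"
  role[grepl("^clin_vol_", nm)] <- "volumetric"
  role[grepl("^clin_cat_", nm)] <- "categorical"
  role[nm == "icv"] <- "icv"
  role[grepl("^rad_", nm)] <- "radiomics"
  role[nm == "stage"] <- "stage"
  role[nm == "time_days"] <- "time"
  role[nm == "event"] <- "event"
  names(role) <- nm
  feature_schema(role)
}

#' Read / write a schema YAML file
#'
#' The YAML maps column names to the role vocabulary of [feature_schema()].
#' @param path file path.
#' @param schema a [feature_schema()].
#' @export
read_schema <- function(path) {
  feature_schema(unlist(yaml::read_yaml(path)))
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(as.list(unclass(schema)), path)
  invisible(path)
}

#' One-hot encode a categorical column
#'
#' Levels are fixed at fitting time (sorted observed levels of the fitting
#' values); values unseen at transform time map to an all-zero row, and
#' missing values propagate as all-\code{NA} rows.
#'
#' @param x vector of categorical values.
#' @param levels fitted level set; \code{NULL} fits on \code{x}.
#' @param name column name used in messages and output column names.
#' @return indicator matrix with attribute \code{levels}.
#' @export
encode_one_hot <- function(x, levels = NULL, name = "x") {
  if (is.null(levels)) {
    levels <- sort(unique(as.character(x[!is.na(x)])))
    if (length(levels) == 0L) {
      stop("cannot one-hot encode column '", name, "': no observed level", call. = FALSE)
    }
  }
  out <- matrix(0, nrow = length(x), ncol = length(levels),
                dimnames = list(NULL, paste0(name, "=", levels)))
  xc <- as.character(x)
  for (k in seq_along(levels)) out[, k] <- as.numeric(xc == levels[k])
  out[is.na(xc), ] <- NA
  attr(out, "levels") <- levels
  out
}

#' Normalize a numeric column
#'
#' \code{zscore} subtracts the fitted mean and divides by the fitted SD
#' (for unbounded measurements); \code{max} divides by the fitted maximum
#' (for bounded measurements such as cognitive scores). Statistics are
#' fitted on the non-missing values of \code{x} when \code{stats} is
#' \code{NULL}, otherwise reused so that held-out rows are transformed
#' without refitting.
#'
#' @param x numeric vector (may contain \code{NA}).
#' @param method "zscore" or "max".
#' @param stats fitted statistics from a previous call (its \code{stats}
#'   attribute), or \code{NULL} to fit.
#' @param name column name for error messages.
#' @return normalized vector with attribute \code{stats}.
#' @export
normalize_numeric <- function(x, method = c("zscore", "max"), stats = NULL,
                              name = "x") {
  method <- match.arg(method)
  if (is.null(stats)) {
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) stop("column '", name, "' has no observed value", call. = FALSE)
    if (method == "zscore") {
      s <- stats::sd(obs)
      if (!is.finite(s) || s == 0) {
        stop("z-score normalization undefined for constant column '", name, "'", call. = FALSE)
      }
      stats <- list(method = "zscore", mean = mean(obs), sd = s)
    } else {
      m <- max(obs)
      if (m == 0) stop("max normalization undefined for column '", name, "' with max 0", call. = FALSE)
      stats <- list(method = "max", max = m)
    }
  }
  out <- if (stats$method == "zscore") (x - stats$mean) / stats$sd else x / stats$max
  attr(out, "stats") <- stats
  out
}

#' Scale volumetric biomarkers by intracranial volume
#'
#' @param volumes numeric vector or matrix of volumes.
#' @param icv per-subject intracranial volume (> 0).
#' @param subject_id optional ids for error messages.
#' @return volumes divided row-wise by ICV.
#' @export
scale_volumetrics_by_icv <- function(volumes, icv, subject_id = NULL) {
  bad <- which(!is.na(icv) & icv <= 0)
  if (length(bad)) {
    id <- if (!is.null(subject_id)) subject_id[bad[1]] else bad[1]
    stop("nonpositive ICV for subject ", id, call. = FALSE)
  }
  if (is.matrix(volumes)) volumes / icv else volumes / icv
}

#' Derive time-to-event from a diagnosis visit history
#'
#' Given longitudinal visits (subject, day, diagnosis), the conversion time
#' of a subject diagnosed MCI at baseline is the span from the baseline
#' visit to the first visit at which AD is observed (event = 1). Subjects
#' never observed as AD are censored at their most recent visit
#' (event = 0). Subjects already AD at baseline, or with no follow-up
#' visit, are rejected with a reason code.
#'
#' @param visits data.frame with columns \code{subject_id}, \code{day}
#'   (numeric, days), \code{diagnosis} (character; \code{"AD"} marks
#'   conversion, anything else is non-AD).
#' @return data.frame (subject_id, time_days, event) for accepted
#'   subjects, with attribute \code{rejected}: data.frame
#'   (subject_id, reason) where reason is \code{"AD_at_baseline"} or
#'   \code{"no_followup"}.
#' @export
derive_time_to_event <- function(visits) {
  stopifnot(all(c("subject_id", "day", "diagnosis") %in% names(visits)))
  out <- list(); rej <- list()
  for (sid in unique(visits$subject_id)) {
    v <- visits[visits$subject_id == sid, , drop = FALSE]
    v <- v[order(v$day), , drop = FALSE]
    base <- v[1L, ]
    if (identical(base$diagnosis, "AD")) {
      rej[[sid]] <- "AD_at_baseline"
      next
    }
    if (nrow(v) < 2L) {
      rej[[sid]] <- "no_followup"
      next
    }
    ad <- which(v$diagnosis == "AD")
    if (length(ad)) {
      out[[sid]] <- c(v$day[ad[1L]] - base$day, 1)
    } else {
      out[[sid]] <- c(v$day[nrow(v)] - base$day, 0)
    }
  }
  res <- data.frame(
    subject_id = names(out),
    time_days = vapply(out, `[`, numeric(1), 1L),
    event = as.integer(vapply(out, `[`, numeric(1), 2L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "rejected") <- data.frame(
    subject_id = names(rej),
    reason = unlist(rej, use.names = FALSE) %||% character(0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res
}
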