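#' Specify a synthetic MCI cohort
#'
#' Defines the generative model for a synthetic cohort of mild cognitive
#' impairment (MCI) subjects: a clinical feature block (mixed
#' numeric/categorical, including two volumetric biomarkers and intracranial
#' volume), a block-correlated radiomics feature block, an eMCI/lMCI stage
#' label correlated with the latent hazard, and a Weibull
#' proportional-hazards time to Alzheimer's conversion under uniform
#' administrative censoring.
#'
#' The latent log-relative hazard of subject \eqn{i} is
#' \deqn{r_i = u_i^c \beta_c + u_i^r \beta_r + \delta \cdot \mathrm{stage}_i}
#' where \eqn{u^c, u^r} are standardized latent clinical and radiomics
#' features, and the stage label is drawn with log-odds
#' \eqn{\mathrm{logit}(p_{lMCI}) + a (u_i^c \beta_c + u_i^r \beta_r)} so that
#' late-stage subjects carry systematically higher risk. Event times follow
#' \eqn{S(t \mid r) = \exp\{-(t/\lambda)^k e^{r}\}} and censoring times are
#' uniform on \eqn{(0, c_{max})}.
#'
#' Default effect sizes, censoring horizon and stage shift are calibrated so
#' that the default cohort shows strong predictable signal and per-stage
#' censoring close to the 92\% (eMCI) / 55\% (lMCI) rates typical of
#' observed MCI-to-AD conversion cohorts.
#'
#' @param n_subjects number of subjects.
#' @param frac_lmci target fraction of late-MCI subjects, in \[0, 1\].
#' @param n_clinical_numeric number of latent numeric clinical signals
#'   (>= 1). When >= 4 the last two are expressed as volumetric biomarkers
#'   multiplied by a per-subject intracranial volume, and when >= 3 one is
#'   expressed as a bounded cognitive score on \[0, 30\].
#' @param n_clinical_categorical number of categorical clinical noise
#'   columns (2--4 levels each; they carry no hazard signal).
#' @param n_radiomics number of radiomics features; correlated in blocks of
#'   5 with within-block correlation \code{radiomics_rho}.
#' @param beta_clinical,beta_radiomics log-hazard effect vectors for the
#'   latent clinical and radiomics features.
#' @param stage_shift additive log-hazard for lMCI subjects (>= 0).
#' @param stage_assoc slope linking the feature-driven risk to the stage
#'   log-odds; 0 makes the stage label independent of the features.
#' @param baseline_scale,baseline_shape Weibull scale (days) and shape.
#' @param censor_time_max administrative censoring horizon in days.
#' @param missing_rate MCAR missingness rate applied to clinical columns.
#' @param radiomics_rho within-block correlation of the radiomics block.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   cohort.
#' @return an object of class \code{cohort_spec}.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 800,
                        frac_lmci = 0.63,
                        n_clinical_numeric = 6,
                        n_clinical_categorical = 2,
                        n_radiomics = 20,
                        beta_clinical = rep_len(c(0.9, -0.7, 0.6, 0.6, -0.7, 0.6), n_clinical_numeric),
                        beta_radiomics = {
                          b <- numeric(n_radiomics)
                          b[intersect(c(1L, 6L, 11L), seq_len(n_radiomics))] <-
                            c(0.7, -0.6, 0.6)[seq_along(intersect(c(1L, 6L, 11L), seq_len(n_radiomics)))]
                          b
                        },
                        stage_shift = 0.5,
                        stage_assoc = 2.0,
                        baseline_scale = 5000,
                        baseline_shape = 1.3,
                        censor_time_max = 2400,
                        missing_rate = 0.1,
                        radiomics_rho = 0.35,
                        seed = 1L) {
  spec <- list(
    n_subjects = n_subjects, frac_lmci = frac_lmci,
    n_clinical_numeric = n_clinical_numeric,
    n_clinical_categorical = n_clinical_categorical,
    n_radiomics = n_radiomics,
    beta_clinical = as.numeric(beta_clinical),
    beta_radiomics = as.numeric(beta_radiomics),
    stage_shift = stage_shift, stage_assoc = stage_assoc,
    baseline_scale = baseline_scale, baseline_shape = baseline_shape,
    censor_time_max = censor_time_max, missing_rate = missing_rate,
    radiomics_rho = radiomics_rho, seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk_count <- function(field, min = 1) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min || v != round(v)) {
      stop_config(field, sprintf("must be an integer >= %d", min))
    }
  }
  chk_count("n_subjects")
  chk_count("n_clinical_numeric")
  chk_count("n_clinical_categorical", min = 0)
  chk_count("n_radiomics")
  if (spec$frac_lmci < 0 || spec$frac_lmci > 1) stop_config("frac_lmci", "must lie in [0, 1]")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) stop_config("missing_rate", "must lie in [0, 1)")
  if (spec$baseline_scale <= 0) stop_config("baseline_scale", "must be > 0")
  if (spec$baseline_shape <= 0) stop_config("baseline_shape", "must be > 0")
  if (spec$censor_time_max <= 0) stop_config("censor_time_max", "must be > 0")
  if (spec$stage_shift < 0) stop_config("stage_shift", "must be >= 0")
  if (length(spec$beta_clinical) != spec$n_clinical_numeric) {
    stop_config("beta_clinical", "length must equal n_clinical_numeric")
  }
  if (length(spec$beta_radiomics) != spec$n_radiomics) {
    stop_config("beta_radiomics", "length must equal n_radiomics")
  }
  if (spec$radiomics_rho < 0 || spec$radiomics_rho >= 1) {
    stop_config("radiomics_rho", "must lie in [0, 1)")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic MCI cohort spec: %d subjects (%.0f%% lMCI), %d+%d clinical, %d radiomics\n",
    x$n_subjects, 100 * x$frac_lmci, x$n_clinical_numeric,
    x$n_clinical_categorical, x$n_radiomics
  ))
  cat(sprintf(
    "  Weibull(scale=%g d, shape=%g), stage shift %g, censoring U(0, %g d), missing %g, seed %d\n",
    x$baseline_scale, x$baseline_shape, x$stage_shift,
    x$censor_time_max, x$missing_rate, x$seed
  ))
  invisible(x)
}

# Draw a block-correlated standard Gaussian matrix (blocks of 5, equi-
# correlation rho within a block) via a shared block factor.
rnorm_block <- function(n, p, rho, block = 5L) {
  if (rho == 0) return(matrix(stats::rnorm(n * p), n, p))
  z <- matrix(stats::rnorm(n * p), n, p)
  nb <- ceiling(p / block)
  f <- matrix(stats::rnorm(n * nb), n, nb)
  for (j in seq_len(p)) {
    b <- (j - 1L) %/% block + 1L
    z[, j] <- sqrt(rho) * f[, b] + sqrt(1 - rho) * z[, j]
  }
  z
}

#' Generate a synthetic MCI cohort
#'
#' Draws a seeded cohort from a [cohort_spec()]. The returned data frame
#' carries, per subject: observable clinical columns (prefix \code{clin_},
#' affine transforms of the latent signals; volumetric columns are the
#' latent ratio multiplied by the subject's \code{icv}), the radiomics block
#' (prefix \code{rad_}), the stage label (\code{stage}, 0 = eMCI,
#' 1 = lMCI), the observed follow-up time \code{time_days}, the event
#' indicator \code{event} (1 = converted to AD), and hidden ground-truth
#' columns (\code{latent_risk} and the standardized latent features,
#' prefix \code{latent_}) retained for oracle checks only.
#'
#' MCAR missingness at the spec's \code{missing_rate} is injected into the
#' observable clinical columns; radiomics, \code{icv}, stage, time and event
#' are never masked.
#'
#' @param spec a [cohort_spec()].
#' @return a \code{data.frame} of class \code{cohort_table} with attribute
#'   \code{schema} describing column roles (see [default_schema()]).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  pc <- spec$n_clinical_numeric
  pr <- spec$n_radiomics

  with_seed(spec$seed, {
    u_clin <- matrix(stats::rnorm(n * pc), n, pc)
    u_rad <- rnorm_block(n, pr, spec$radiomics_rho)

    risk0 <- drop(u_clin %*% spec$beta_clinical + u_rad %*% spec$beta_radiomics)
    # Intercept solved so the marginal lMCI fraction matches the spec even
    # when the slope makes the logistic mean shrink toward 1/2.
    slope_term <- spec$stage_assoc * (risk0 - mean(risk0))
    target <- min(max(spec$frac_lmci, 1e-6), 1 - 1e-6)
    a0 <- stats::uniroot(function(a) mean(stats::plogis(a + slope_term)) - target,
                         interval = c(-30, 30))$root
    stage <- stats::rbinom(n, 1L, stats::plogis(a0 + slope_term))
    latent_risk <- risk0 + spec$stage_shift * stage

    # Weibull PH: S(t | r) = exp(-(t/scale)^shape * e^r)
    u <- stats::runif(n)
    t_event <- spec$baseline_scale * (-log(u) / exp(latent_risk))^(1 / spec$baseline_shape)
    t_cens <- stats::runif(n, 0, spec$censor_time_max)
    time_days <- pmax(pmin(t_event, t_cens), 0.5)
    event <- as.integer(t_event <= t_cens)

    # Observable clinical columns: affine re-expressions of the latent
    # signals, so that standardization recovers them.
    n_vol <- if (pc >= 4L) 2L else 0L
    has_bounded <- pc >= 3L
    icv <- stats::rnorm(n, 1.5e6, 1.2e5)
    clin <- list()
    schema_roles <- character()
    for (j in seq_len(pc)) {
      if (n_vol > 0L && j > pc - n_vol) {
        k <- j - (pc - n_vol)
        nm <- paste0("clin_vol_", k)
        clin[[nm]] <- (0.02 + 0.002 * u_clin[, j]) * icv
        schema_roles[nm] <- "volumetric"
      } else if (has_bounded && j == 1L) {
        nm <- "clin_mmse"
        clin[[nm]] <- pmin(30, pmax(0, 26 + 2.5 * u_clin[, j]))
        schema_roles[nm] <- "bounded_numeric"
      } else {
        nm <- paste0("clin_num_", j)
        clin[[nm]] <- 70 + 6 * u_clin[, j]
        schema_roles[nm] <- "unbounded_numeric"
      }
    }
    for (j in seq_len(spec$n_clinical_categorical)) {
      nm <- paste0("clin_cat_", j)
      nlev <- 2L + (j - 1L) %% 3L
      clin[[nm]] <- sample(LETTERS[seq_len(nlev)], n, replace = TRUE)
      schema_roles[nm] <- "categorical"
    }

    rad <- 10 + 2 * u_rad
    colnames(rad) <- paste0("rad_", seq_len(pr))

    tab <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      clin, icv = icv, rad,
      stage = stage, time_days = time_days, event = event,
      latent_risk = latent_risk,
      stats::setNames(as.data.frame(u_clin), paste0("latent_clin_", seq_len(pc))),
      stats::setNames(as.data.frame(u_rad), paste0("latent_rad_", seq_len(pr))),
      stringsAsFactors = FALSE
    )
    schema_roles["icv"] <- "icv"
    class(tab) <- c("cohort_table", "data.frame")
    attr(tab, "clinical_roles") <- schema_roles
    if (spec$missing_rate > 0) {
      tab <- inject_missingness(tab, spec$missing_rate,
                                seed = derive_seed(spec$seed, "missingness"))
    }
    tab
  })
}

clinical_columns <- function(table) {
  grep("^clin_", names(table), value = TRUE)
}

#' Inject MCAR missingness into the clinical block
#'
#' Each observable clinical cell (columns prefixed \code{clin_}) is set
#' missing independently with probability \code{rate}. Radiomics columns,
#' \code{icv}, stage, time and event are never masked.
#'
#' @param table a cohort table.
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return the table with missing clinical cells.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop_config("rate", "must lie in [0, 1)")
  }
  if (rate == 0) return(table)
  cols <- clinical_columns(table)
  with_seed(seed, {
    for (nm in cols) {
      mask <- stats::runif(nrow(table)) < rate
      table[[nm]][mask] <- NA
    }
  })
  table
}

#' Extract the hidden ground-truth risk of a synthetic cohort
#'
#' @param table a cohort table produced by [generate_cohort()].
#' @return the latent log-relative-hazard vector.
#' @export
true_risk <- function(table) {
  if (!("latent_risk" %in% names(table))) {
    stop("table has no hidden 'latent_risk' column; ",
         "true_risk() is only defined for synthetic cohorts generated with truth retained",
         call. = FALSE)
  }
  table$latent_risk
}

#' Write / read a cohort CSV
#'
#' The CSV uses the package's column-naming convention (\code{clin_*},
#' \code{rad_*}, \code{icv}, \code{stage}, \code{time_days}, \code{event}).
#' Hidden truth columns (\code{latent_*}) are written only when
#' \code{with_truth = TRUE}.
#'
#' @param table a cohort table.
#' @param path output path.
#' @param with_truth keep the hidden ground-truth columns.
#' @export
write_cohort <- function(table, path, with_truth = FALSE) {
  out <- as.data.frame(table)
  if (!with_truth) out <- out[, !grepl("^latent_", names(out)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
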