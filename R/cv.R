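# Stratified k-fold cross-validation.

#' Stratified fold assignment
#'
#' Subjects are stratified jointly on (stage, event) and dealt round-robin
#' within each stratum after a seeded shuffle, so every fold carries both
#' classes and events in proportion.
#'
#' @param stage,event label vectors.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per subject.
#' @export
make_folds <- function(stage, event, k = 5L, seed = 1L) {
  n <- length(stage)
  if (k < 2L || k > n) stop_config("k", "must lie in [2, n]")
  fold <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    for (s in unique(paste(stage, event))) {
      idx <- which(paste(stage, event) == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(stage[tr])) < 2L || sum(event[tr]) == 0L) {
      stop("infeasible stratification: a training split lacks a class or an event; ",
           "use a smaller k", call. = FALSE)
    }
  }
  fold
}

fold_metrics <- function(fit_pred, test_pred, test, horizon) {
  ci <- concordance_index(test_pred$risk, test$time, test$event)
  bs <- ipcw_brier(test_pred$risk, fit_pred$baseline, test$time, test$event, horizon)
  pt <- predict_survival_time(test_pred$risk, fit_pred$baseline)
  mae <- time_mae(pt, test$time, test$event)
  cr <- classification_report(test_pred$p_lmci, test$stage)
  c(CI = ci, BS = bs, MAE_days = mae,
    Acc = cr$Acc, AP = cr$AP, Pre = cr$Pre, Rec = cr$Rec, F1 = cr$F1, AUC = cr$AUC)
}

#' k-fold cross-validated evaluation of the multitask model
#'
#' For each fold: preprocessing statistics, the imputation regressions,
#' the model and the Breslow baseline hazard are all fitted on the
#' training split only (audited with [assert_no_leakage()]); metrics are
#' computed on the held-out fold. The Brier horizon defaults to the median
#' uncensored event time of each training fold.
#'
#' @param table a cohort table.
#' @param schema a [feature_schema()]; default [default_schema()].
#' @param config a [model_config()].
#' @param control a [train_control()].
#' @param k number of folds (default 5).
#' @param seed seed governing folds, initialization and dropout.
#' @param horizon fixed Brier horizon in days, or \code{NULL} for the
#'   per-fold default.
#' @param checkpoint_dir if non-\code{NULL}, completed folds are saved
#'   there and reloaded on re-run, so an interrupted run resumes.
#' @return object of class \code{cv_report}: per-fold metrics, their mean,
#'   per-subject held-out predictions, and per-fold training histories.
#' @export
cross_validate <- function(table, schema = default_schema(table),
                           config = model_config(), control = train_control(),
                           k = 5L, seed = 1L, horizon = NULL,
                           checkpoint_dir = NULL) {
  roles <- schema[names(schema) %in% names(table)]
  stage_all <- table[[names(roles)[roles == "stage"]]]
  event_all <- table[[names(roles)[roles == "event"]]]
  fold <- make_folds(stage_all, event_all, k = k, seed = seed)

  fold_rows <- vector("list", k)
  predictions <- vector("list", k)
  histories <- vector("list", k)
  provenance <- vector("list", k)

  for (f in seq_len(k)) {
    ckpt <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("fold_%02d.rds", f))
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      res <- readRDS(ckpt)
    } else {
      res <- run_cv_fold(table, schema, config, control, fold, f, seed, horizon)
      if (!is.null(ckpt)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(res, ckpt)
      }
    }
    fold_rows[[f]] <- res$metrics
    predictions[[f]] <- res$predictions
    histories[[f]] <- res$history
    provenance[[f]] <- res$provenance
  }

  folds_df <- data.frame(fold = seq_len(k), do.call(rbind, fold_rows))
  structure(list(
    folds = folds_df,
    mean = colMeans(folds_df[, -1L, drop = FALSE]),
    predictions = do.call(rbind, predictions),
    histories = histories,
    provenance = provenance,
    fold_assignment = fold,
    config = config, k = k, seed = seed
  ), class = "cv_report")
}

run_cv_fold <- function(table, schema, config, control, fold, f, seed, horizon) {
  train_ids <- which(fold != f)
  test_ids <- which(fold == f)
  design <- build_design_matrices(table, schema, fit_ids = train_ids,
                                  seed = derive_seed(seed, paste0("impute", f)))
  assert_no_leakage(design, test_ids)

  ctl <- control
  ctl$seed <- derive_seed(seed, paste0("fold", f))
  fit <- span_mtl(design$clinical[train_ids, , drop = FALSE],
                  if (!is.null(design$radiomics)) design$radiomics[train_ids, , drop = FALSE],
                  design$stage[train_ids], design$time[train_ids],
                  design$event[train_ids], config = config, control = ctl)

  test_pred <- model_forward(design$clinical[test_ids, , drop = FALSE],
                             if (!is.null(design$radiomics)) design$radiomics[test_ids, , drop = FALSE],
                             fit$params, training = FALSE)
  test <- list(stage = design$stage[test_ids], time = design$time[test_ids],
               event = design$event[test_ids])
  h <- horizon %||% stats::median(design$time[train_ids][design$event[train_ids] == 1])
  metrics <- fold_metrics(fit, test_pred, test, h)

  predictions <- data.frame(
    subject_id = design$subject_id[test_ids], fold = f,
    p_lmci = test_pred$p_lmci, risk = test_pred$risk,
    predicted_days = predict_survival_time(test_pred$risk, fit$baseline),
    stage = test$stage, time_days = test$time, event = test$event,
    stringsAsFactors = FALSE
  )
  # provenance tags: which rows every fitted statistic, imputation
  # regression and the baseline hazard were computed on
  provenance <- list(
    fold = f, test_ids = test_ids,
    stats_fit_ids = design$stats$fit_ids,
    impute_fit_rows = design$stats$impute$fit_rows,
    baseline_fit_ids = train_ids
  )
  list(metrics = metrics, predictions = predictions, history = fit$history,
       provenance = provenance)
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold cross-validation (%s encoder, %s fusion), seed %d\n",
              x$k, x$config$encoder, x$config$fusion, x$seed))
  print(round(x$folds, digits))
  cat("mean:\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' Write a cross-validation report to CSV and JSON
#'
#' @param report a \code{cv_report}.
#' @param dir output directory (created if missing).
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$folds, file.path(dir, "metrics_folds.csv"), row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"), row.names = FALSE)
  for (f in seq_along(report$histories)) {
    utils::write.csv(report$histories[[f]],
                     file.path(dir, sprintf("history_fold_%02d.csv", f)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(mean = as.list(report$mean),
         folds = report$folds,
         k = report$k, seed = report$seed,
         fusion = report$config$fusion, encoder = report$config$encoder),
    file.path(dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
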