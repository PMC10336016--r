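#' Fit the multimodal multitask MCI model
#'
#' Trains the two-branch encoder-fusion network on preprocessed design
#' matrices: a SPAN (or MLP-baseline) block per modality, AED gated or
#' concatenation fusion, and a shared fully connected head feeding a
#' sigmoid eMCI/lMCI classifier and a linear Cox-style log-relative hazard
#' score, optimized jointly by binary cross-entropy plus the negative log
#' partial likelihood with full-batch risk sets. A Breslow baseline hazard
#' is fitted on the training risk scores so the model can translate risks
#' into predicted conversion times.
#'
#' @param clinical numeric design matrix (subjects x features), no missing
#'   values; see [build_design_matrices()].
#' @param radiomics numeric design matrix, or \code{NULL} for a
#'   clinical-only configuration.
#' @param stage binary stage labels (0 = eMCI, 1 = lMCI).
#' @param time,event survival records (days; 1 = converted to AD).
#' @param config a [model_config()].
#' @param control a [train_control()].
#' @return object of class \code{span_mtl}.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_subjects = 120, seed = 3))
#' dm <- build_design_matrices(tab, default_schema(tab))
#' fit <- span_mtl(dm$clinical, dm$radiomics, dm$stage, dm$time, dm$event,
#'                 config = model_config(widths = c(16L, 8L), fc_widths = 8L),
#'                 control = train_control(epochs = 30L, lr = 5e-3))
#' print(fit)
#' head(predict(fit, type = "risk"))
#' @export
span_mtl <- function(clinical, radiomics = NULL, stage, time, event,
                     config = model_config(), control = train_control()) {
  stopifnot(inherits(config, "model_config"), inherits(control, "train_control"))
  clinical <- as.matrix(clinical)
  if (!is.null(radiomics)) radiomics <- as.matrix(radiomics)
  if (config$fusion != "clinical_only" && is.null(radiomics)) {
    stop_config("fusion", sprintf("'%s' requires a radiomics matrix", config$fusion))
  }
  n <- nrow(clinical)
  stopifnot(length(stage) == n, length(time) == n, length(event) == n)

  params0 <- init_params(config, ncol(clinical),
                         if (!is.null(radiomics)) ncol(radiomics) else 1L,
                         seed = control$seed)
  trained <- train_model(params0, clinical, radiomics, stage, time, event, control)

  pred <- model_forward(clinical, radiomics, trained$params, training = FALSE)
  baseline <- breslow_baseline(pred$risk, time, event)

  structure(list(
    params = trained$params,
    config = config,
    control = control,
    history = trained$history,
    baseline = baseline,
    fitted = pred,
    data = list(clinical = clinical, radiomics = radiomics,
                stage = stage, time = time, event = event),
    call = match.call()
  ), class = "span_mtl")
}

#' @export
print.span_mtl <- function(x, ...) {
  n <- length(x$data$stage)
  cat(sprintf("Multimodal multitask MCI model (%s encoder, %s fusion)\n",
              x$config$encoder, x$config$fusion))
  cat(sprintf("  %d subjects, %d events (%.1f%% censored), %d + %d input features\n",
              n, sum(x$data$event), 100 * mean(x$data$event == 0),
              ncol(x$data$clinical),
              if (!is.null(x$data$radiomics)) ncol(x$data$radiomics) else 0L))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs: BCE %.4f, Cox NLL %.4f, total %.4f\n",
              nrow(x$history), h$loss_bce, h$loss_cox, h$loss_total))
  invisible(x)
}

#' @export
summary.span_mtl <- function(object, ...) {
  print(object)
  d <- object$data
  ci <- concordance_index(object$fitted$risk, d$time, d$event)
  cr <- classification_report(object$fitted$p_lmci, d$stage)
  cat(sprintf("  apparent (training) concordance %.3f, accuracy %.3f, AUC %.3f\n",
              ci, cr$Acc, cr$AUC))
  if (!is.null(object$fitted$tau)) {
    cat(sprintf("  AED gate tau: median %.3f (range %.3f-%.3f)\n",
                stats::median(object$fitted$tau), min(object$fitted$tau),
                max(object$fitted$tau)))
  }
  invisible(object)
}

#' @export
coef.span_mtl <- function(object, ...) {
  object$params
}

#' Predict from a fitted multitask model
#'
#' @param object a [span_mtl()] fit.
#' @param clinical,radiomics design matrices; defaults to the training
#'   data. They must be preprocessed with statistics fitted on the
#'   training split (see [build_design_matrices()]).
#' @param type "risk" (log-relative hazard), "prob" (lMCI probability),
#'   "time" (median predicted conversion days from the training Breslow
#'   baseline), or "tau" (AED gate values; AED fusion only).
#' @param ... unused.
#' @export
predict.span_mtl <- function(object, clinical = NULL, radiomics = NULL,
                             type = c("risk", "prob", "time", "tau"), ...) {
  type <- match.arg(type)
  if (is.null(clinical)) {
    clinical <- object$data$clinical
    radiomics <- object$data$radiomics
  }
  pred <- model_forward(clinical, radiomics, object$params, training = FALSE)
  switch(type,
    risk = pred$risk,
    prob = pred$p_lmci,
    time = predict_survival_time(pred$risk, object$baseline),
    tau = {
      if (is.null(pred$tau)) stop("tau is only defined under AED fusion", call. = FALSE)
      pred$tau
    }
  )
}

#' @export
residuals.span_mtl <- function(object, type = c("martingale"), ...) {
  type <- match.arg(type)
  d <- object$data
  d$event - cumhaz_at(object$baseline, d$time) * exp(object$fitted$risk)
}

#' @export
plot.span_mtl <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss_bce, h$loss_cox, h$loss_total),
                    type = "l", lty = 1, col = c("steelblue", "firebrick", "black"),
                    xlab = "epoch", ylab = "loss",
                    main = "Training loss components", ...)
  graphics::legend("topright", c("BCE", "Cox NLL", "total"),
                   col = c("steelblue", "firebrick", "black"), lty = 1, bty = "n")
  invisible(x)
}
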