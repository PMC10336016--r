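#' Training control
#'
#' @param lr learning rate of the adaptive-moment (Adam) optimizer.
#' @param epochs maximum epochs (>= 1).
#' @param patience epochs without loss improvement before early stop.
#' @param weights loss-term weights (classification, survival).
#' @param batch_size \code{NULL} for full-batch risk sets (default; ranking
#'   terms see the whole cohort each step) or a mini-batch size with
#'   within-batch risk sets.
#' @param weight_decay decoupled L2 weight decay applied at each step.
#' @param val_fraction fraction of the training data held out as an
#'   internal validation split used to checkpoint the best epoch; 0
#'   disables validation and monitors the training loss instead.
#' @param seed seed governing dropout, shuffling and the validation split.
#' @param verbose print the loss every 50 epochs.
#' @export
train_control <- function(lr = 5e-3, epochs = 400L, patience = 400L,
                          weights = c(1, 1), batch_size = NULL,
                          weight_decay = 0.1, val_fraction = 0.2,
                          seed = 1L, verbose = FALSE) {
  if (lr < 0) stop_config("lr", "must be >= 0")
  if (epochs < 1) stop_config("epochs", "must be >= 1")
  if (val_fraction < 0 || val_fraction >= 0.5) {
    stop_config("val_fraction", "must lie in [0, 0.5)")
  }
  structure(list(lr = lr, epochs = as.integer(epochs),
                 patience = as.integer(patience), weights = weights,
                 batch_size = batch_size, weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_control")
}

loss_adjoints <- function(pred, y, time, event, weights) {
  n <- length(y)
  d_logit <- weights[1] * (pred$p_lmci - y) / n
  d_risk <- weights[2] * cox_partial_nll_grad(pred$risk, time, event)
  list(d_logit = d_logit, d_risk = d_risk)
}

# Stratified internal validation split (on stage x event).
val_split <- function(stage, event, fraction, seed) {
  if (fraction <= 0) return(NULL)
  n <- length(stage)
  val <- with_seed(derive_seed(seed, "valsplit"), {
    idx <- integer(0)
    for (s in unique(paste(stage, event))) {
      members <- which(paste(stage, event) == s)
      take <- floor(length(members) * fraction)
      if (take > 0) idx <- c(idx, sample(members, take))
    }
    sort(idx)
  })
  # validation CI needs an event and a comparable pair
  if (sum(event[val]) < 1L || length(val) < 5L || sum(event[-val]) < 1L) return(NULL)
  val
}

#' Train the multitask model
#'
#' Gradient-based minimization of [total_loss()] with Adam plus decoupled
#' weight decay. By default every step uses the full training batch so
#' that the partial-likelihood risk sets span the whole cohort, and a
#' stratified internal validation split checkpoints the epoch with the
#' best validation concordance, guarding the ranking task against
#' overfitting.
#'
#' @param params initial [init_params()].
#' @param clinical,radiomics design matrices.
#' @param stage,time,event labels and survival records.
#' @param control a [train_control()].
#' @return list: trained \code{params} (best checkpoint) and a per-epoch
#'   \code{history} data.frame (epoch, loss_bce, loss_cox, loss_total,
#'   val_ci).
#' @export
train_model <- function(params, clinical, radiomics, stage, time, event,
                        control = train_control()) {
  if (sum(event == 1) == 0L) {
    stop("training split has no uncensored subject; survival loss undefined",
         call. = FALSE)
  }
  val <- val_split(stage, event, control$val_fraction, control$seed)
  fit_idx <- if (is.null(val)) seq_along(stage) else setdiff(seq_along(stage), val)
  clin_f <- clinical[fit_idx, , drop = FALSE]
  rad_f <- if (!is.null(radiomics)) radiomics[fit_idx, , drop = FALSE]
  y_f <- stage[fit_idx]; t_f <- time[fit_idx]; e_f <- event[fit_idx]

  theta <- params_to_vec(params)
  mask <- grad_mask_vec(params)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- length(y_f)
  history <- matrix(NA_real_, control$epochs, 4L)
  best <- list(score = -Inf, theta = theta, epoch = 0L)
  step <- 0L

  for (epoch in seq_len(control$epochs)) {
    cur <- vec_to_params(theta, params)
    ep_seed <- derive_seed(control$seed, paste0("epoch", epoch))

    batches <- if (is.null(control$batch_size)) {
      list(seq_len(n))
    } else {
      idx <- with_seed(derive_seed(ep_seed, "shuffle"), sample.int(n))
      split(idx, ceiling(seq_along(idx) / control$batch_size))
    }

    ep_bce <- ep_cox <- 0; used <- 0L
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      if (sum(e_f[b] == 1) == 0L) next  # ranking loss needs an event
      pred <- model_forward(clin_f[b, , drop = FALSE],
                            if (!is.null(rad_f)) rad_f[b, , drop = FALSE],
                            cur, training = TRUE,
                            seed = derive_seed(ep_seed, paste0("batch", bi)),
                            keep_cache = TRUE)
      l_b <- bce_loss(pred$p_lmci, y_f[b])
      l_c <- cox_partial_nll(pred$risk, t_f[b], e_f[b])
      adj <- loss_adjoints(pred, y_f[b], t_f[b], e_f[b], control$weights)
      g <- model_backward(cur, pred$cache, adj$d_logit, adj$d_risk)
      gvec <- params_to_vec(g[names(params)])
      if (!is.null(mask)) gvec <- gvec * mask

      step <- step + 1L
      m <- b1 * m + (1 - b1) * gvec
      v <- b2 * v + (1 - b2) * gvec^2
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      theta <- theta - control$lr * (mh / (sqrt(vh) + eps) + control$weight_decay * theta)
      cur <- vec_to_params(theta, params)
      ep_bce <- ep_bce + l_b * length(b); ep_cox <- ep_cox + l_c * length(b)
      used <- used + length(b)
    }
    l_bce <- ep_bce / used; l_cox <- ep_cox / used
    l_tot <- control$weights[1] * l_bce + control$weights[2] * l_cox

    val_ci <- NA_real_
    score <- -l_tot
    if (!is.null(val)) {
      vp <- model_forward(clinical[val, , drop = FALSE],
                          if (!is.null(radiomics)) radiomics[val, , drop = FALSE],
                          cur, training = FALSE)
      val_ci <- concordance_index(vp$risk, time[val], event[val])
      val_auc <- tryCatch(
        suppressWarnings(classification_report(vp$p_lmci, stage[val])$AUC),
        error = function(e) NA_real_
      )
      # both tasks share the trunk; checkpoint an epoch good for both
      score <- if (is.finite(val_auc)) (val_ci + val_auc) / 2 else val_ci
    }
    history[epoch, ] <- c(l_bce, l_cox, l_tot, val_ci)
    if (control$verbose && epoch %% 50L == 0L) {
      message(sprintf("epoch %4d  bce %.4f  cox %.4f  total %.4f  val CI %.3f",
                      epoch, l_bce, l_cox, l_tot, val_ci))
    }
    if (score > best$score + 1e-7) {
      best <- list(score = score, theta = theta, epoch = epoch)
    } else if (epoch - best$epoch >= control$patience) {
      history <- history[seq_len(epoch), , drop = FALSE]
      break
    }
  }
  history <- history[stats::complete.cases(history[, 1:3, drop = FALSE]), , drop = FALSE]
  list(
    params = vec_to_params(best$theta, params),
    history = data.frame(epoch = seq_len(nrow(history)),
                         loss_bce = history[, 1], loss_cox = history[, 2],
                         loss_total = history[, 3], val_ci = history[, 4])
  )
}
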