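# Survival and classification metrics.

#' Harrell's concordance index
#'
#' Over comparable pairs (i, j) with \eqn{T_i < T_j} and \eqn{E_i = 1},
#' counts pairs where the earlier-failing subject carries the higher risk;
#' risk ties earn half credit. Pairs tied on time are not comparable under
#' this convention.
#'
#' @param risk risk scores (higher = earlier expected event).
#' @param time,event survival records.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cmp <- outer(time, time, `<`) & (event == 1)
  n_cmp <- sum(cmp)
  if (n_cmp == 0L) stop("no comparable pairs", call. = FALSE)
  conc <- sum(cmp & outer(risk, risk, `>`)) + 0.5 * sum(cmp & outer(risk, risk, `==`))
  conc / n_cmp
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' At each distinct event time \eqn{t}, the hazard increment is
#' \eqn{d_t / \sum_{j: T_j \ge t} e^{r_j}}, cumulated into a nondecreasing
#' step function.
#'
#' @param risk training risk scores.
#' @param time,event training survival records.
#' @return object of class \code{breslow_baseline}: data.frame with
#'   \code{time}, \code{hazard} (increment) and \code{cumhaz}.
#' @export
breslow_baseline <- function(risk, time, event) {
  if (sum(event == 1) == 0L) {
    stop("Breslow estimator undefined with zero uncensored subjects", call. = FALSE)
  }
  m <- max(risk)
  er <- exp(risk - m)
  ev_times <- sort(unique(time[event == 1]))
  inc <- vapply(ev_times, function(t) {
    sum(time[event == 1] == t) / (sum(er[time >= t]) * exp(m))
  }, numeric(1))
  structure(
    data.frame(time = ev_times, hazard = inc, cumhaz = cumsum(inc)),
    class = c("breslow_baseline", "data.frame")
  )
}

cumhaz_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$time)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Predicted survival probability at given times
#'
#' \eqn{S_i(t) = \exp\{-H_0(t) e^{r_i}\}} from a Breslow baseline.
#'
#' @param risk risk scores.
#' @param baseline a [breslow_baseline()].
#' @param times evaluation times (recycled against risk if scalar).
#' @export
predict_survival_prob <- function(risk, baseline, times) {
  exp(-outer(exp(risk), cumhaz_at(baseline, times)))
}

#' Predicted conversion time (median survival)
#'
#' The first baseline event time at which the subject's predicted survival
#' drops to 0.5 or below; if it never does within the observed range, the
#' largest observed event time (right-truncation convention). Predictions
#' are antitone in risk.
#'
#' @param risk risk scores.
#' @param baseline a [breslow_baseline()].
#' @return predicted days.
#' @export
predict_survival_time <- function(risk, baseline) {
  if (nrow(baseline) == 0L) stop("empty baseline hazard", call. = FALSE)
  # S(t) <= 0.5  <=>  H0(t) >= log(2) * exp(-risk)
  thresh <- log(2) * exp(-risk)
  vapply(thresh, function(th) {
    hit <- which(baseline$cumhaz >= th)
    if (length(hit)) baseline$time[hit[1L]] else max(baseline$time)
  }, numeric(1))
}

#' Mean absolute error of predicted conversion times
#'
#' Computed over uncensored subjects only; censored subjects have no
#' observed conversion time to compare against.
#'
#' @param predicted predicted days.
#' @param time,event observed records.
#' @return MAE in days.
#' @export
time_mae <- function(predicted, time, event) {
  if (sum(event == 1) == 0L) stop("no uncensored subjects", call. = FALSE)
  mean(abs(predicted - time)[event == 1])
}

# Kaplan-Meier censoring-survival curve as a right-continuous function.
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  sf <- stats::stepfun(fit$time, c(1, fit$surv))
  list(at = function(t) sf(t), left = function(t) sf(t - 1e-8))
}

#' Inverse-probability-of-censoring-weighted Brier score
#'
#' Squared error between the event indicator at the horizon and the
#' predicted survival probability, reweighted by the Kaplan-Meier
#' censoring-survival curve: subjects observed to fail by the horizon
#' contribute with weight \eqn{1/G(T_i^-)}, subjects still under
#' observation with weight \eqn{1/G(t^*)}, and subjects censored before
#' the horizon contribute zero. With no censoring this reduces to the
#' plain Brier score.
#'
#' @param risk risk scores of the evaluated subjects.
#' @param baseline a [breslow_baseline()] fitted on training data.
#' @param time,event survival records of the evaluated subjects.
#' @param horizon evaluation time \eqn{t^*} in days.
#' @param cens_time,cens_event records used for the censoring curve
#'   (default: the evaluated subjects).
#' @return Brier score in \[0, 1\].
#' @export
ipcw_brier <- function(risk, baseline, time, event, horizon,
                       cens_time = time, cens_event = event) {
  G <- censoring_km(cens_time, cens_event)
  s_hat <- drop(predict_survival_prob(risk, baseline, horizon))
  failed <- time <= horizon & event == 1
  at_risk <- time > horizon
  w <- numeric(length(time))
  if (any(failed)) {
    g <- G$left(time[failed])
    if (any(g <= 0)) stop("censoring survival zero at an event time", call. = FALSE)
    w[failed] <- 1 / g
  }
  if (any(at_risk)) {
    g <- G$at(horizon)
    if (g <= 0) stop("censoring survival zero at the horizon", call. = FALSE)
    w[at_risk] <- 1 / g
  }
  mean(w * (as.numeric(at_risk) - s_hat)^2)
}

#' Classification metrics for the stage task
#'
#' Standard definitions with the positive class = lMCI (label 1) and
#' probabilities at the threshold predicted positive. AUC is the
#' Mann-Whitney statistic (ties half credit); AP is the step-wise average
#' precision over distinct thresholds. With a single observed class AUC
#' and AP are undefined and returned as \code{NA} with a warning.
#'
#' @param p predicted probabilities.
#' @param y binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return named list: Acc, AP, Pre, Rec, F1, AUC.
#' @export
classification_report <- function(p, y, threshold = 0.5) {
  stopifnot(length(p) == length(y))
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  acc <- mean(pred == y)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0

  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC and AP undefined with a single observed class")
    auc <- ap <- NA_real_
  } else {
    r <- rank(p)
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    # average precision over distinct thresholds, descending
    ord <- order(-p)
    ps <- p[ord]; ys <- y[ord]
    ctp <- cumsum(ys); cpp <- seq_along(ys)
    last_of_thresh <- !duplicated(ps, fromLast = TRUE)
    prec <- (ctp / cpp)[last_of_thresh]
    recall <- (ctp / n1)[last_of_thresh]
    ap <- sum(diff(c(0, recall)) * prec)
  }
  list(Acc = acc, AP = ap, Pre = pre, Rec = rec, F1 = f1, AUC = auc)
}
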