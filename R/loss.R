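# Joint objective: binary cross-entropy for the stage classifier plus the
# negative log Cox partial likelihood for the hazard score, summed with
# equal weight by default.

#' Binary cross-entropy
#'
#' \deqn{-\frac{1}{M}\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]}
#' with probabilities clamped to \[1e-7, 1 - 1e-7\].
#'
#' @param p predicted probabilities in \[0, 1\].
#' @param y binary labels.
#' @return scalar loss.
#' @export
bce_loss <- function(p, y) {
  if (length(p) != length(y)) stop("p and y lengths differ", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Shared machinery for the partial likelihood: per-subject log risk-set
# mass and cumulative event weights, Breslow convention for ties (all
# subjects with T_j >= T_i are in i's risk set, ties included).
cox_risk_sets <- function(risk, time, event) {
  n <- length(risk)
  m <- max(risk)
  er <- exp(risk - m)
  ord <- order(time)
  er_s <- er[ord]; t_s <- time[ord]; e_s <- event[ord]
  # S_i = sum_{j: T_j >= T_i} exp(r_j - m); within a tied-time group every
  # member gets the sum from the group's first position.
  revcum <- rev(cumsum(rev(er_s)))
  S <- stats::ave(revcum, t_s, FUN = max)
  # cumulative event weight sum_{i: E_i = 1, T_i <= T_k} 1/S_i
  w <- ifelse(e_s == 1, 1 / S, 0)
  cumw <- stats::ave(cumsum(w), t_s, FUN = max)
  list(ord = ord, er_s = er_s, t_s = t_s, e_s = e_s, S = S, cumw = cumw, m = m)
}

#' Negative log Cox partial likelihood
#'
#' \deqn{-\frac{1}{M_{E=1}} \sum_{i: E_i = 1}
#'   \left( r_i - \log \sum_{j: T_j \ge T_i} e^{r_j} \right)}
#' averaged over uncensored subjects, with risk sets taken at each event
#' time (the subject included), a numerically stable log-sum-exp, and the
#' Breslow convention for tied event times. The loss is invariant to
#' adding a constant to all risks and to permuting subjects.
#'
#' @param risk log-relative hazard scores.
#' @param time observed times (> 0).
#' @param event event indicators in \{0, 1\}.
#' @return scalar loss.
#' @export
cox_partial_nll <- function(risk, time, event) {
  if (length(unique(c(length(risk), length(time), length(event)))) != 1L) {
    stop("risk, time and event lengths differ", call. = FALSE)
  }
  n_ev <- sum(event == 1)
  if (n_ev == 0L) {
    stop("Cox partial likelihood undefined with zero uncensored subjects",
         call. = FALSE)
  }
  rs <- cox_risk_sets(risk, time, event)
  r_s <- risk[rs$ord]
  -sum((r_s - (rs$m + log(rs$S)))[rs$e_s == 1]) / n_ev
}

# Gradient of cox_partial_nll w.r.t. the risk vector:
# dL/dr_k = -(1/Me) (E_k - e^{r_k} sum_{i: E_i=1, T_i <= T_k} 1/S_i).
cox_partial_nll_grad <- function(risk, time, event) {
  n_ev <- sum(event == 1)
  rs <- cox_risk_sets(risk, time, event)
  g_s <- -(rs$e_s - rs$er_s * rs$cumw) / n_ev
  g <- numeric(length(risk))
  g[rs$ord] <- g_s
  g
}

#' Joint multitask loss
#'
#' Weighted sum of the classification and survival objectives; the default
#' weights (1, 1) add the two losses unmodified.
#'
#' @param p predicted lMCI probabilities.
#' @param y stage labels.
#' @param risk hazard scores.
#' @param time,event survival records.
#' @param weights length-2 vector (classification, survival).
#' @return scalar with attributes \code{bce} and \code{cox}.
#' @export
total_loss <- function(p, y, risk, time, event, weights = c(1, 1)) {
  l_bce <- bce_loss(p, y)
  l_cox <- cox_partial_nll(risk, time, event)
  structure(weights[1] * l_bce + weights[2] * l_cox, bce = l_bce, cox = l_cox)
}
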