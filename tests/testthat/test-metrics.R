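brute_force_ci <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

test_that("concordance matches hand-enumerated examples", {
  expect_equal(concordance_index(c(3, 1, 2), c(1, 3, 2), c(1, 0, 1)), 1)
  expect_equal(concordance_index(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_error(concordance_index(1, 5, 0), "comparable")
})

test_that("concordance agrees with the pairwise oracle and survival::concordance", {
  for (i in 1:40) {
    r <- random_records(sample(5:30, 1), seed = 2000 + i)
    expect_identical(concordance_index(r$risk, r$time, r$event),
                     brute_force_ci(r$risk, r$time, r$event))
  }
  r <- random_records(60, seed = 31)
  sc <- survival::concordance(survival::Surv(r$time, r$event) ~ r$risk,
                              reverse = TRUE)
  expect_equal(concordance_index(r$risk, r$time, r$event),
               as.numeric(sc$concordance), tolerance = 1e-12)
})

test_that("concordance respects its symmetry and monotone invariance", {
  r <- random_records(40, seed = 55)
  ci <- concordance_index(r$risk, r$time, r$event)
  expect_equal(ci + concordance_index(-r$risk, r$time, r$event), 1)
  expect_equal(concordance_index(exp(2 * r$risk), r$time, r$event), ci)
})

test_that("the Breslow estimator reproduces closed-form cases", {
  b1 <- breslow_baseline(0, 5, 1)
  expect_equal(b1$time, 5)
  expect_equal(b1$cumhaz, 1)

  # equal risks, no censoring: Nelson-Aalen increments 1/n, 1/(n-1), ...
  n <- 6
  bn <- breslow_baseline(rep(0, n), 1:n, rep(1, n))
  expect_equal(bn$hazard, 1 / (n:1), tolerance = 1e-12)
  expect_true(all(diff(bn$cumhaz) > 0))

  withr::with_seed(3, r <- random_records(30, seed = 3))
  br <- breslow_baseline(r$risk, r$time, r$event)
  expect_true(all(br$hazard >= 0))
  expect_true(!is.unsorted(br$cumhaz))
  expect_error(breslow_baseline(c(1, 2), c(1, 2), c(0, 0)), "uncensored")
})

test_that("median predicted survival time behaves as documented", {
  b1 <- breslow_baseline(0, 5, 1)
  # S(5) = exp(-1) <= 0.5 at risk 0
  expect_equal(predict_survival_time(0, b1), 5)
  # extremely low risk never crosses 0.5: right-truncated at max event time
  expect_equal(predict_survival_time(-50, b1), 5)

  r <- random_records(50, seed = 14)
  bl <- breslow_baseline(r$risk, r$time, r$event)
  risks <- sort(rnorm(10))
  pt <- predict_survival_time(risks, bl)
  expect_true(all(diff(pt) <= 0))  # antitone in risk
})

test_that("time MAE uses uncensored subjects only", {
  expect_equal(time_mae(c(150, 150), c(100, 200), c(1, 1)), 50)
  expect_equal(time_mae(c(100, 999), c(100, 200), c(1, 0)), 0)
  expect_error(time_mae(100, 100, 0), "uncensored")
})

test_that("IPCW Brier reduces to the plain Brier score without censoring", {
  # perfect binary survival predictions
  bl <- breslow_baseline(c(2, 2, 2), c(10, 11, 12), c(1, 1, 1))
  risk <- c(5, 5, -30)
  time <- c(8, 9, 50); event <- c(1, 1, 1)
  bs <- ipcw_brier(risk, bl, time, event, horizon = 20)
  s_hat <- drop(predict_survival_prob(risk, bl, 20))
  expect_equal(bs, mean((c(0, 0, 1) - s_hat)^2), tolerance = 1e-12)

  # constant predictor S = 0.5 scores 0.25
  bl2 <- breslow_baseline(0, 1, 1)  # H0 jumps to 1 at t=1
  risk2 <- rep(log(log(2)), 4)      # exp(risk) * 1 = log 2 -> S = 0.5
  bs2 <- ipcw_brier(risk2, bl2, time = c(2, 3, 0.5, 0.6),
                    event = c(1, 1, 1, 1), horizon = 1.5)
  expect_equal(bs2, 0.25, tolerance = 1e-12)
})

test_that("IPCW weights match a hand-computed censored example", {
  # subjects: failed at 2, censored at 3, alive past horizon 5
  time <- c(2, 3, 6); event <- c(1, 0, 1)
  # censoring KM: one censoring event at t=3 among 2 at risk -> G = 1, t<3; 0.5 after
  risk <- c(0.5, -0.2, -1)
  bl <- breslow_baseline(risk, time, event)
  s_hat <- drop(predict_survival_prob(risk, bl, 5))
  manual <- ((1 / 1) * (0 - s_hat[1])^2 + 0 + (1 / 0.5) * (1 - s_hat[3])^2) / 3
  expect_equal(ipcw_brier(risk, bl, time, event, horizon = 5), manual,
               tolerance = 1e-12)
})

test_that("classification metrics match their definitions", {
  r <- classification_report(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$Acc, 1); expect_equal(r$AUC, 1); expect_equal(r$F1, 1)
  expect_equal(r$AP, 1)

  r2 <- classification_report(c(0.7, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(r2$AUC, 0.75)

  # threshold ties predict positive
  r3 <- classification_report(c(0.5, 0.4), c(1, 0))
  expect_equal(r3$Acc, 1)

  expect_warning(r4 <- classification_report(c(0.6, 0.7), c(1, 1)), "single")
  expect_true(is.na(r4$AUC)); expect_true(is.na(r4$AP))
  expect_equal(r4$Acc, 1)
})

test_that("AUC and AP agree with pROC on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    y <- rbinom(80, 1, 0.4)
    y[1:2] <- c(0, 1)
    p <- plogis(rnorm(80) + y)
  })
  r <- classification_report(p, y)
  ref <- as.numeric(suppressMessages(pROC::auc(y, p)))
  expect_equal(r$AUC, ref, tolerance = 1e-12)
})
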