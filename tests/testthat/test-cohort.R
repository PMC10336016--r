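test_that("the same spec and seed reproduce the cohort bit for bit", {
  s <- tiny_spec(n = 100, seed = 7)
  expect_identical(generate_cohort(s), generate_cohort(s))
})

test_that("invalid spec fields are rejected by name", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(frac_lmci = 1.2), "frac_lmci")
  expect_error(cohort_spec(baseline_scale = -1), "baseline_scale")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(beta_clinical = c(1, 2)), "beta_clinical")
})

test_that("zero effect sizes leave the latent risk uncorrelated with features", {
  s <- tiny_spec(n = 400, seed = 5,
                 beta_clinical = rep(0, 6), beta_radiomics = rep(0, 20),
                 stage_assoc = 0, missing_rate = 0)
  tab <- generate_cohort(s)
  # risk is constant within each stage
  expect_equal(stats::sd(tab$latent_risk[tab$stage == 0]), 0)
  expect_equal(stats::sd(tab$latent_risk[tab$stage == 1]), 0)
  k <- stats::cor(tab$latent_risk, tab$latent_clin_1, method = "kendall")
  expect_lt(abs(k), 0.1)
})

test_that("stage shift raises the mean latent risk of lMCI subjects", {
  tab <- generate_cohort(tiny_spec(n = 300, seed = 2, stage_shift = 1))
  expect_gt(mean(tab$latent_risk[tab$stage == 1]),
            mean(tab$latent_risk[tab$stage == 0]))
})

test_that("the empirical censoring rate falls as the censoring horizon grows", {
  rates <- vapply(c(800, 1600, 2400, 4800), function(cmax) {
    tab <- generate_cohort(tiny_spec(n = 600, seed = 9, censor_time_max = cmax,
                                     missing_rate = 0))
    mean(tab$event == 0)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("MCAR injection hits the target rate and never touches labels", {
  tab <- generate_cohort(tiny_spec(n = 1500, seed = 4, missing_rate = 0))
  masked <- inject_missingness(tab, 0.2, seed = 8)
  cols <- grep("^clin_", names(tab), value = TRUE)
  cells <- unlist(lapply(cols, function(nm) is.na(masked[[nm]])))
  expect_gt(length(cells), 10000)
  expect_lt(abs(mean(cells) - 0.2), 0.02)
  expect_false(anyNA(masked$stage))
  expect_false(anyNA(masked$time_days))
  expect_false(anyNA(masked$event))
  expect_false(anyNA(masked$icv))
  expect_false(anyNA(masked[grep("^rad_", names(masked))]))
})

test_that("zero missingness rate is the identity and rate >= 1 errors", {
  tab <- generate_cohort(tiny_spec(n = 50, seed = 1, missing_rate = 0))
  expect_identical(inject_missingness(tab, 0), tab)
  expect_error(inject_missingness(tab, 1), "rate")
})

test_that("true_risk returns the hidden column and errors without it", {
  tab <- generate_cohort(tiny_spec(n = 40, seed = 6))
  expect_identical(true_risk(tab), tab$latent_risk)
  stripped <- tab[, !grepl("^latent_", names(tab))]
  expect_error(true_risk(stripped), "latent_risk")
})

test_that("the true risk outranks permuted risks on a strong-signal cohort", {
  tab <- generate_cohort(tiny_spec(n = 400, seed = 10, missing_rate = 0))
  ci_true <- concordance_index(true_risk(tab), tab$time_days, tab$event)
  ci_perm <- vapply(1:20, function(i) {
    withr::with_seed(i, concordance_index(sample(true_risk(tab)),
                                          tab$time_days, tab$event))
  }, numeric(1))
  expect_true(all(ci_true > ci_perm))
  expect_gt(ci_true, 0.8)
})

test_that("cohort CSV round-trips, hiding truth columns unless asked", {
  tab <- generate_cohort(tiny_spec(n = 30, seed = 12))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, f1)
  write_cohort(tab, f2, with_truth = TRUE)
  back <- read_cohort(f1)
  expect_false(any(grepl("^latent_", names(back))))
  backt <- read_cohort(f2)
  expect_true("latent_risk" %in% names(backt))
  expect_equal(backt$time_days, tab$time_days, tolerance = 1e-12)
})
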