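test_that("one-hot encoding follows the fitted level set", {
  enc <- encode_one_hot(c("A", "B", "C", "B"), name = "g")
  expect_equal(unname(enc[2, ]), c(0, 1, 0))
  expect_equal(colnames(enc), c("g=A", "g=B", "g=C"))

  single <- encode_one_hot(rep("X", 4))
  expect_equal(unname(single[, 1]), rep(1, 4))

  unseen <- encode_one_hot("D", levels = c("A", "B", "C"))
  expect_equal(unname(unseen[1, ]), c(0, 0, 0))

  na_row <- encode_one_hot(c("A", NA), levels = c("A", "B"))
  expect_true(all(is.na(na_row[2, ])))
  expect_error(encode_one_hot(c(NA, NA), name = "bad"), "bad")
})

test_that("normalization fits on the fitting values and is reusable", {
  z <- normalize_numeric(c(1, 2, 3), "zscore")
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)

  m <- normalize_numeric(c(30, 15), "max")
  expect_equal(as.numeric(m), c(1, 0.5))

  # held-out transform reuses fitted statistics, no refit
  st <- attr(normalize_numeric(c(10, 20, 30), "zscore"), "stats")
  held <- normalize_numeric(c(40, 50), "zscore", stats = st)
  expect_equal(as.numeric(held), (c(40, 50) - 20) / 10)

  expect_error(normalize_numeric(rep(5, 3), "zscore", name = "flat"), "flat")
  expect_error(normalize_numeric(c(0, 0), "max", name = "zz"), "zz")
})

test_that("volumetric scaling divides by the subject's ICV", {
  expect_equal(scale_volumetrics_by_icv(7200, 1.5e6), 0.0048)
  expect_equal(scale_volumetrics_by_icv(0, 2e6), 0)
  expect_error(scale_volumetrics_by_icv(10, 0, subject_id = "S7"), "S7")
})

test_that("time-to-event follows first-AD / last-visit rules", {
  visits <- data.frame(
    subject_id = c("a", "a", "b", "b", "b", "c", "c", "c", "d", "e", "e"),
    day = c(0, 730, 0, 500, 1095, 0, 365, 730, 0, 0, 200),
    diagnosis = c("MCI", "AD", "MCI", "MCI", "MCI", "MCI", "AD", "AD", "MCI",
                  "AD", "AD"),
    stringsAsFactors = FALSE
  )
  res <- derive_time_to_event(visits)
  expect_equal(res$time_days[res$subject_id == "a"], 730)
  expect_equal(res$event[res$subject_id == "a"], 1L)
  expect_equal(res$time_days[res$subject_id == "b"], 1095)
  expect_equal(res$event[res$subject_id == "b"], 0L)
  # first AD observation counts, not later ones
  expect_equal(res$time_days[res$subject_id == "c"], 365)

  rej <- attr(res, "rejected")
  expect_setequal(rej$subject_id, c("d", "e"))
  expect_equal(rej$reason[rej$subject_id == "d"], "no_followup")
  expect_equal(rej$reason[rej$subject_id == "e"], "AD_at_baseline")

  # order independence w.r.t. visit record shuffling
  shuffled <- visits[withr::with_seed(1, sample(nrow(visits))), ]
  res2 <- derive_time_to_event(shuffled)
  expect_equal(res2[order(res2$subject_id), ], res[order(res$subject_id), ],
               ignore_attr = TRUE)
})

test_that("design build is deterministic and complete", {
  tab <- generate_cohort(tiny_spec(n = 150, seed = 7))
  dm1 <- build_design_matrices(tab, default_schema(tab), seed = 2)
  dm2 <- build_design_matrices(tab, default_schema(tab), seed = 2)
  expect_identical(dm1$clinical, dm2$clinical)
  expect_identical(dm1$radiomics, dm2$radiomics)
  expect_false(anyNA(dm1$clinical))
  expect_true(all(is.finite(dm1$clinical)))
  expect_true(all(is.finite(dm1$radiomics)))
})

test_that("statistics are fitted on the fitting split only", {
  tab <- generate_cohort(tiny_spec(n = 200, seed = 8, missing_rate = 0))
  fit_ids <- 1:120
  dm <- build_design_matrices(tab, default_schema(tab), fit_ids = fit_ids)
  # fitting rows are standardized; held-out rows keep their shift
  zcol <- dm$clinical[, "clin_num_2"]
  expect_equal(mean(zcol[fit_ids]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(zcol[fit_ids]), 1, tolerance = 1e-10)
  expect_false(abs(mean(zcol[-fit_ids])) < 1e-10)
  expect_identical(dm$stats$fit_ids, fit_ids)
  expect_silent(assert_no_leakage(dm, 121:200))
  expect_error(assert_no_leakage(dm, 120:200), "held-out")
})

test_that("columns not covered by the schema are reported", {
  tab <- generate_cohort(tiny_spec(n = 30, seed = 1))
  sch <- default_schema(tab)
  sch2 <- feature_schema(unclass(sch)[names(sch) != "rad_1"])
  expect_error(build_design_matrices(tab, sch2), "rad_1")
})

test_that("schema YAML round-trips", {
  tab <- generate_cohort(tiny_spec(n = 20, seed = 1))
  sch <- default_schema(tab)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, f)
  expect_equal(unclass(read_schema(f)), unclass(sch))
})
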