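test_that("the AED gate reproduces its forced and saturated cases", {
  d <- 4
  params <- structure(list(U = matrix(1, d, d), W = matrix(0, d, d),
                           b = rep(0, d)), class = "aed_params")
  # zero input, zero gate weights: h = 1, sigmoid(0) = 0.5 exactly
  expect_identical(aed_factor(matrix(0, 3, d), params), rep(0.5, 3))

  params$b <- rep(20, d)
  withr::with_seed(1, I <- matrix(rnorm(3 * d), 3, d))
  expect_equal(aed_factor(I, params), rep(1, 3), tolerance = 1e-8)

  expect_error(aed_factor(matrix(0, 2, 3), params), "width")
})

test_that("the gate equals an independent step-by-step recomputation", {
  withr::with_seed(6, {
    d <- 5; g <- 4
    params <- structure(list(U = matrix(rnorm(g * d), g, d),
                             W = matrix(rnorm(g * g), g, g),
                             b = rnorm(g)), class = "aed_params")
    I <- matrix(rnorm(7 * d), 7, d)
  })
  tau <- aed_factor(I, params)
  manual <- vapply(seq_len(nrow(I)), function(i) {
    h <- exp(-pmax(drop(params$U %*% I[i, ]), 0))
    max(1 / (1 + exp(-(drop(params$W %*% h) + params$b))))
  }, numeric(1))
  expect_equal(tau, manual, tolerance = 1e-12)
  expect_true(all(tau > 0 & tau < 1))
})

test_that("AED fusion is a per-sample convex combination", {
  withr::with_seed(8, {
    d <- 6
    params <- structure(list(U = matrix(rnorm(d * d), d, d),
                             W = matrix(rnorm(d * d), d, d),
                             b = rnorm(d)), class = "aed_params")
    Ic <- matrix(rnorm(20 * d), 20, d)
    Ir <- matrix(rnorm(20 * d), 20, d)
  })
  fz <- aed_fuse(Ic, Ir, params)
  lo <- pmin(Ic, Ir); hi <- pmax(Ic, Ir)
  expect_true(all(fz$fused >= lo - 1e-12 & fz$fused <= hi + 1e-12))

  # equal branch inputs are a fixed point for any tau
  fe <- aed_fuse(Ic, Ic, params)
  expect_equal(fe$fused, Ic, ignore_attr = TRUE)
  expect_error(aed_fuse(Ic, Ir[, 1:3], params), "equal branch widths")
})

test_that("concatenation fusion stacks clinical first and round-trips", {
  a <- matrix(1, 2, 3); b <- matrix(2, 2, 4)
  out <- concat_fuse(a, b)
  expect_equal(dim(out), c(2, 7))
  expect_equal(out[, 1:3], a, ignore_attr = TRUE)
  expect_equal(out[, 4:7], b, ignore_attr = TRUE)
})

test_that("a zero network predicts indifference", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 7, seed = 1)
  theta <- rep(0, length(mcispan:::params_to_vec(p)))
  p0 <- mcispan:::vec_to_params(theta, p)
  withr::with_seed(2, {
    clin <- matrix(rnorm(4 * 5), 4, 5)
    rad <- matrix(rnorm(4 * 7), 4, 7)
  })
  pr <- model_forward(clin, rad, p0)
  expect_equal(pr$p_lmci, rep(0.5, 4))
  expect_equal(pr$risk, rep(0, 4))
})

test_that("evaluation-mode forward passes are deterministic", {
  dm <- tiny_design(n = 40, seed = 5)
  p <- init_params(tiny_model_config(), ncol(dm$clinical), ncol(dm$radiomics), 3)
  a <- model_forward(dm$clinical, dm$radiomics, p)
  b <- model_forward(dm$clinical, dm$radiomics, p)
  expect_identical(a, b)
  expect_true(all(a$p_lmci > 0 & a$p_lmci < 1))
  expect_true(all(a$tau > 0 & a$tau < 1))
  expect_error(model_forward(dm$clinical[1:3, ], dm$radiomics, p), "row counts")
})

test_that("initialization is seeded and validates widths", {
  cfg <- tiny_model_config()
  expect_identical(init_params(cfg, 4, 6, seed = 1), init_params(cfg, 4, 6, seed = 1))
  expect_false(identical(init_params(cfg, 4, 6, seed = 1),
                         init_params(cfg, 4, 6, seed = 2)))
  expect_error(model_config(widths_clinical = c(8L), widths_radiomics = c(6L)),
               "widths")
})

test_that("random inputs stay finite through the exponential gate", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 6, 6, seed = 9)
  withr::with_seed(11, {
    clin <- matrix(rnorm(1000 * 6, sd = 3), 1000, 6)
    rad <- matrix(rnorm(1000 * 6, sd = 3), 1000, 6)
  })
  pr <- model_forward(clin, rad, p)
  expect_true(all(is.finite(pr$p_lmci)))
  expect_true(all(is.finite(pr$risk)))
  expect_true(all(pr$tau > 0 & pr$tau < 1))
})

test_that("unimodal configurations bypass fusion", {
  dm <- tiny_design(n = 30, seed = 2)
  for (fus in c("clinical_only", "radiomics_only")) {
    p <- init_params(tiny_model_config(fusion = fus),
                     ncol(dm$clinical), ncol(dm$radiomics), 4)
    pr <- model_forward(dm$clinical, dm$radiomics, p)
    expect_null(pr$tau)
    expect_length(pr$risk, 30)
  }
})
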