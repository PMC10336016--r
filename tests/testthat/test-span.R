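test_that("affine projection matches direct matrix arithmetic", {
  expect_equal(unname(affine_project(c(2, 3), diag(2), c(0, 0))),
               matrix(c(2, 3), 1))
  expect_equal(unname(affine_project(c(0, 0), diag(2), c(4, -1))),
               matrix(c(4, -1), 1))
  withr::with_seed(3, {
    Z <- matrix(rnorm(12), 3, 4)
    W <- matrix(rnorm(8), 2, 4)
    b <- rnorm(2)
  })
  expect_equal(affine_project(Z, W, b),
               t(W %*% t(Z) + b), ignore_attr = TRUE)
  expect_error(affine_project(Z, matrix(0, 2, 3), c(0, 0)), "shape")
})

test_that("polynomial expansion builds componentwise powers", {
  xs <- polynomial_expand(c(2, 3), 3)
  expect_equal(lapply(xs, as.numeric), list(c(2, 3), c(4, 9), c(8, 27)))

  ones <- polynomial_expand(matrix(1, 2, 4), 4)
  for (x in ones) expect_true(all(x == 1))

  withr::with_seed(1, X1 <- matrix(rnorm(15), 3, 5))
  pow5 <- X1
  for (k in 1:4) pow5 <- pow5 * X1
  expect_identical(polynomial_expand(X1, 5)[[5]], pow5)
  expect_equal(polynomial_expand(X1, 5)[[5]], X1^5, tolerance = 1e-12)
  expect_error(polynomial_expand(X1, 0), "degree")
})

test_that("attention maps are proper distributions over features", {
  d <- 6
  X <- polynomial_expand(matrix(rnorm(2 * d), 2, d), 2)
  zero_w <- lapply(1:2, function(k) matrix(0, d, d))
  M <- attention_map(X, zero_w, rep(0, d))
  expect_equal(unname(M), matrix(1 / d, 2, d))

  m1 <- attention_map(polynomial_expand(matrix(5, 1, 1), 1),
                      list(matrix(2, 1, 1)), 0.3)
  expect_equal(as.numeric(m1), 1)

  # softmax of logits (1, 2)
  sm <- exp(c(1, 2)) / sum(exp(c(1, 2)))
  expect_equal(round(sm, 5), c(0.26894, 0.73106))

  expect_error(attention_map(X, zero_w[1], rep(0, d)), "per polynomial degree")
})

test_that("one sub-network composes projection, attention and product", {
  # identity projection, zero attention weights on width 2: uniform map 1/2
  p <- poly_attention_params(diag(2), c(0, 0),
                             list(matrix(0, 2, 2), matrix(0, 2, 2)), c(0, 0))
  Z <- matrix(c(2, 3), 1)
  out <- span_subnet_forward(Z, p, activation = "identity")
  expect_equal(unname(out), 0.5 * Z)

  # zero input with zero bias annihilates regardless of attention weights
  pr <- random_subnet(2, 3, 2, seed = 4)
  pr$b_Z <- c(0, 0, 0)
  expect_equal(unname(span_subnet_forward(matrix(0, 1, 2), pr)),
               matrix(0, 1, 3))
  expect_equal(selu(0), 0)
})

test_that("a SPAN stack is the documented composition with SELU on top", {
  d <- 3
  zero_sub <- function() {
    poly_attention_params(diag(d), rep(0, d),
                          lapply(1:2, function(k) matrix(0, d, d)), rep(0, d))
  }
  stack <- span_stack_params(zero_sub(), zero_sub())
  withr::with_seed(2, Z <- matrix(rnorm(6), 2, d))
  expect_equal(span_forward(Z, stack), selu(Z / d^2), ignore_attr = TRUE)

  # batch independence: a row alone equals the same row inside a batch
  s <- span_stack_params(random_subnet(d, d, 2, 5), random_subnet(d, d, 2, 6))
  all_rows <- span_forward(Z, s)
  one_row <- span_forward(Z[2, , drop = FALSE], s)
  expect_equal(all_rows[2, , drop = FALSE], one_row)
})

test_that("attention rows sum to one across random draws", {
  withr::with_seed(42, {
    worst <- 0
    for (i in 1:100) {
      d <- sample(2:8, 1)
      sub <- random_subnet(d, d, sample(1:3, 1), seed = i)
      Z <- matrix(rnorm(10 * d), 10, d)
      fw <- span_subnet_forward(Z, sub, keep_cache = TRUE)
      worst <- max(worst, abs(rowSums(fw$cache$M) - 1))
    }
  })
  expect_lt(worst, 1e-6)
})

test_that("SPAN blocks are deterministic in evaluation mode", {
  blocks <- list(span_stack_params(random_subnet(4, 3, 2, 1),
                                   random_subnet(3, 3, 2, 2)))
  withr::with_seed(7, Z <- matrix(rnorm(20), 5, 4))
  e1 <- span_block_forward(Z, blocks, dropout_rate = 0.5, training = FALSE, seed = 1)
  e2 <- span_block_forward(Z, blocks, dropout_rate = 0.5, training = FALSE, seed = 999)
  expect_identical(e1, e2)

  # zero dropout: training equals evaluation
  t0 <- span_block_forward(Z, blocks, dropout_rate = 0, training = TRUE, seed = 3)
  expect_identical(t0, e1)

  # seeded dropout mask reproduces
  t1 <- span_block_forward(Z, blocks, dropout_rate = 0.5, training = TRUE, seed = 5)
  t2 <- span_block_forward(Z, blocks, dropout_rate = 0.5, training = TRUE, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, e1))
  expect_error(span_block_forward(Z, blocks, dropout_rate = 1), "dropout_rate")
})

test_that("small input perturbations move the output continuously", {
  s <- span_stack_params(random_subnet(4, 4, 3, 8), random_subnet(4, 4, 3, 9))
  withr::with_seed(10, Z <- matrix(rnorm(8), 2, 4))
  base <- span_forward(Z, s)
  for (eps in c(1e-3, 1e-5)) {
    pert <- span_forward(Z + eps, s)
    expect_lt(max(abs(pert - base)), 100 * eps)
  }
})
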