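test_that("parameter accounting matches the closed-form counts", {
  s <- conv_spec(3, 3, 16, height = 256, width = 256)
  pc <- standard_conv_params(s)
  expect_equal(pc$parameters, 432)
  expect_equal(pc$mult_adds, 28311552)

  expect_equal(standard_conv_params(conv_spec(1, 1, 1))$parameters, 1)

  sp <- separable_conv_params(s)
  expect_equal(sp$parameters, 75) # 27 depthwise + 48 pointwise
  expect_equal(separable_conv_params(conv_spec(1, 1, 1))$parameters, 2)

  s2 <- conv_spec(3, 16, 32, height = 64, width = 64)
  expect_equal(separable_conv_params(s2)$mult_adds, (144 + 512) * 4096)
})

test_that("param_ratio follows 1/N + 1/k^2 and the 8-to-9-fold economy", {
  expect_equal(param_ratio(conv_spec(3, 8, 16)), 1 / 16 + 1 / 9)
  expect_equal(param_ratio(conv_spec(3, 8, 16)), 0.173611, tolerance = 1e-6)
  # degenerate 1x1: separable has MORE parameters
  expect_equal(param_ratio(conv_spec(1, 1, 1)), 2)
  # reciprocal approaches 9 from below for k = 3
  r1024 <- 1 / param_ratio(conv_spec(3, 1024, 1024, 2048, 2048))
  expect_gt(r1024, 8)
  expect_lt(r1024, 9)
  expect_equal(r1024, 8.92, tolerance = 1e-3)
  for (N in c(1L, 2L, 7L, 64L, 513L, 4096L)) {
    s <- conv_spec(3, 5, N, 1024, 1024)
    std <- standard_conv_params(s)$parameters
    sep <- separable_conv_params(s)$parameters
    # exact integer identity with the printed fraction, always < 9-fold
    expect_equal(std / sep, 1 / (1 / N + 1 / 9))
    expect_lt(std / sep, 9)
  }
})

test_that("invalid conv specs are rejected", {
  expect_error(conv_spec(0, 3, 16), "positive")
  expect_error(conv_spec(3, -1, 16), "positive")
  expect_error(conv_spec(3, 1, 1, height = 4, width = 4, dilation_rate = 2),
               "extent")
})

test_that("depthwise reference: identity, impulse and channel contracts", {
  x <- rand_image(6, 6, 3, 1)
  id <- array(0, c(3, 3, 3)); id[2, 2, ] <- 1
  expect_equal(depthwise_conv_ref(x, id), x)

  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  y <- depthwise_conv_ref(imp, matrix(1, 3, 3))
  expect_equal(sum(y), 9)
  expect_equal(y[3:5, 3:5], matrix(1, 3, 3))
  expect_true(all(y[-(3:5), ] == 0))

  expect_error(depthwise_conv_ref(x, array(1, c(3, 3, 2))), "channel")
})

test_that("pointwise reference: identity, channel sum, dimensions", {
  x <- rand_image(5, 4, 2, 2)
  expect_equal(pointwise_conv_ref(x[, , 1, drop = FALSE], matrix(1, 1, 1)),
               x[, , 1, drop = FALSE])
  sums <- pointwise_conv_ref(x, matrix(c(1, 1), 2, 1))
  expect_equal(sums[, , 1], x[, , 1] + x[, , 2])
  expect_equal(dim(pointwise_conv_ref(x, matrix(1, 2, 5))), c(5L, 4L, 5L))
  expect_error(pointwise_conv_ref(x, matrix(1, 3, 1)), "channels")
})

test_that("dilated reference: rate-1 degeneracy and impulse spread", {
  x <- matrix(runif(64), 8, 8)
  k <- matrix(rnorm(9), 3, 3)
  expect_equal(dilated_conv_ref(x, k, rate = 1), depthwise_conv_ref(x, k))

  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  y <- dilated_conv_ref(imp, matrix(1, 3, 3), rate = 2)
  hits <- which(y == 1, arr.ind = TRUE)
  expect_equal(nrow(hits), 9L)
  expect_setequal(unique(hits[, 1] - 5L), c(-2L, 0L, 2L))
  expect_setequal(unique(hits[, 2] - 5L), c(-2L, 0L, 2L))

  expect_identical(effective_kernel_extent(3, 2), 5L)
  expect_identical(effective_kernel_extent(3, 3), 7L)
})

test_that("naive references match the fast layers on seeded random inputs", {
  for (trial in 1:20) {
    set.seed(trial)
    M <- sample(1:4, 1); N <- sample(1:4, 1)
    x <- array(rnorm(8 * 8 * M), c(8, 8, M))
    dw <- array(rnorm(9 * M), c(3, 3, M))
    pw <- matrix(rnorm(M * N), M, N)
    rate <- sample(1:3, 1)

    fast_dw <- ns$cpp_dwconv_fw(ns$as_t4(x), matrix(dw, 9, M), 3L,
                                as.integer(rate))
    expect_lt(max(abs(as.vector(fast_dw) -
                        as.vector(depthwise_conv_ref(x, dw, rate = rate)))),
              1e-5)

    fast_pw <- ns$cpp_conv2d_fw(ns$as_t4(x), pw, 1L, 1L)
    expect_lt(max(abs(as.vector(fast_pw) -
                        as.vector(pointwise_conv_ref(x, pw)))), 1e-5)

    # separable composition: pointwise(depthwise(x))
    fast_sep <- ns$cpp_conv2d_fw(
      ns$cpp_dwconv_fw(ns$as_t4(x), matrix(dw, 9, M), 3L, 1L), pw, 1L, 1L)
    expect_lt(max(abs(as.vector(fast_sep) -
                        as.vector(separable_conv_ref(x, dw, pw)))), 1e-5)

    w <- array(rnorm(9 * M * N), c(3, 3, M, N))
    fast_cv <- ns$cpp_conv2d_fw(ns$as_t4(x), matrix(w, 9 * M, N), 3L,
                                as.integer(rate))
    expect_lt(max(abs(as.vector(fast_cv) -
                        as.vector(full_conv_ref(x, w, rate)))), 1e-5)
  }
})

test_that("formula counts equal instantiated bias-free layer weights", {
  set.seed(99)
  for (trial in 1:10) {
    k <- sample(c(1L, 3L, 5L), 1)
    M <- sample(1:32, 1); N <- sample(1:32, 1)
    s <- conv_spec(k, M, N, height = 64, width = 64)
    w_std <- ns$init_conv_w(k, M, N, "he_normal")
    expect_equal(length(w_std), standard_conv_params(s)$parameters)
    blk <- build_dsc_block(M, N, kernel_size = k)
    expect_equal(dsc_block_params(blk), separable_conv_params(s)$parameters)
  }
})
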