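test_that("DSC block equals the naive separable reference with copied weights", {
  set.seed(8)
  blk <- build_dsc_block(4, 6)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  got <- dsc_block_forward(blk, x)
  dw <- array(blk$params$dw, c(3, 3, 4))
  ref <- separable_conv_ref(x, dw, blk$params$pw)
  expect_lt(max(abs(got - ref)), 1e-4)
  expect_equal(dim(got), c(8L, 8L, 6L))
  expect_equal(dsc_block_params(blk),
               separable_conv_params(conv_spec(3, 4, 6))$parameters)
  expect_error(build_dsc_block(0, 4), "channel")
})

test_that("MDC block: wiring, activations and dilated-conv oracle equivalence", {
  set.seed(9)
  blk <- build_mdc_block(3, 5, rates = c(1, 2, 3))
  # layer graph: each dilated conv is followed by batch_norm then swish
  expect_equal(blk$layers, c(
    "dilated_conv(3x3, rate=1)", "batch_norm", "swish",
    "dilated_conv(3x3, rate=2)", "batch_norm", "swish",
    "dilated_conv(3x3, rate=3)", "batch_norm", "swish"))
  expect_equal(effective_kernel_extent(3, 3), 7L)

  x <- array(runif(9 * 9 * 3), c(9, 9, 3))
  got <- mdc_block_forward(blk, x)
  expect_equal(dim(got), c(9L, 9L, 5L))

  # independent reconstruction from naive references + batch-norm formula
  h <- x
  for (i in 1:3) {
    inp <- if (i == 1) x else {
      arr <- array(0, c(9, 9, 3 + 5))
      arr[, , 1:3] <- x; arr[, , 4:8] <- h
      arr
    }
    w <- array(blk$params[[sprintf("c%d.w", i)]],
               c(3, 3, dim(inp)[3], 5))
    z <- full_conv_ref(inp, w, rate = i)
    z <- bn_fresh_ref(z, blk$params[[sprintf("bn%d.g", i)]],
                      blk$params[[sprintf("bn%d.b", i)]])
    h <- swish(z)
  }
  expect_lt(max(abs(got - h)), 1e-4)
})

test_that("MDC with literal kernel sizes 1/2/3 is available as an alternative", {
  blk <- build_mdc_block(2, 3, mdc_mode = "sizes")
  expect_equal(blk$kernels, c(1L, 2L, 3L))
  expect_equal(blk$rates, c(1L, 1L, 1L))
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_equal(dim(mdc_block_forward(blk, x)), c(8L, 8L, 3L))
})

test_that("model shape contracts hold and generalize across input sizes", {
  set.seed(1)
  cfg <- model_config(input_size = 64L, filter_ladder = c(4L, 8L, 16L, 32L))
  m <- build_model(cfg)
  sc <- make_scene(scene_spec(size = 64, seed = 1))
  p <- model_forward(m, sc$image)
  expect_equal(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))

  sm <- summarize(m)
  expect_equal(sm$bottleneck_spatial, c(4L, 4L)) # 64 / 2^4
  expect_equal(sm$n_pool_layers, 4L)
  # encoder halves spatial size at each stage; decoder restores it
  expect_equal(sm$shapes[["enc1.pool"]][1:2], c(32L, 32L))
  expect_equal(sm$shapes[["enc2.pool"]][1:2], c(16L, 16L))
  expect_equal(sm$shapes[["dec1.out"]][1:2], c(64L, 64L))
  # stage concatenation width = 3 * ladder
  expect_equal(sm$shapes[["enc1.concat"]][3], 12L)
  expect_equal(sm$total_parameters, count_params(m))

  expect_error(model_config(input_size = 100L), "divisible")
})

test_that("separable blocks strictly reduce the parameter count", {
  set.seed(2)
  cfg_sep <- model_config(input_size = 32L, filter_ladder = c(4L, 8L))
  cfg_std <- model_config(input_size = 32L, filter_ladder = c(4L, 8L),
                          use_separable = FALSE)
  n_sep <- count_params(build_model(cfg_sep))
  n_std <- count_params(build_model(cfg_std))
  expect_lt(n_sep, n_std)
})

test_that("a fixed global seed reproduces initial weights bit-for-bit", {
  cfg <- tiny_model_config()
  set.seed(123); m1 <- build_model(cfg)
  set.seed(123); m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  set.seed(124); m3 <- build_model(cfg)
  expect_false(identical(m1$params, m3$params))
})

test_that("all-Glorot initialization variant is available", {
  cfg <- model_config(input_size = 16L, filter_ladder = c(2L, 3L),
                      bottleneck_filters = 4L, init_scheme = "glorot_all")
  set.seed(1)
  m <- build_model(cfg)
  # Glorot draws are bounded; He-normal draws are not bounded by the limit
  w <- m$params[["enc1.mdc.c1.w"]]
  lim <- sqrt(6 / (9 * 3 + 9 * 2))
  expect_true(all(abs(w) <= lim))
})

test_that("checkpoints round-trip through save/load", {
  set.seed(3)
  m <- build_model(tiny_model_config())
  x <- rand_image(16, 16, 3, 5)
  p1 <- model_forward(m, x)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m$params, m2$params)
  expect_equal(model_forward(m2, x), p1)
  unlink(f)
})
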