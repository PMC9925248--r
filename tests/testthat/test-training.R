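make_tiny_set <- function(n, seed = 1) {
  make_dataset(n, scene_spec(size = 16), seed = seed)
}

test_that("history bookkeeping and seeded reproducibility", {
  set.seed(50)
  m <- build_model(tiny_model_config())
  ds <- make_tiny_set(4)
  fit <- train(m, ds, train_config(epochs = 1L, batch_size = 2L, seed = 7))
  expect_equal(nrow(fit$history), 1L)
  expect_named(fit$history, c("epoch", "loss", "accuracy"))

  set.seed(50)
  m2 <- build_model(tiny_model_config())
  fit2 <- train(m2, ds, train_config(epochs = 1L, batch_size = 2L, seed = 7))
  expect_identical(fit$history$loss, fit2$history$loss)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("training loss descends on a small synthetic set", {
  set.seed(60)
  m <- build_model(tiny_model_config())
  ds <- make_tiny_set(8, seed = 2)
  fit <- train(m, ds, train_config(epochs = 8L, batch_size = 4L, seed = 3))
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  # descent sanity: large majority of epoch-to-epoch steps decrease
  steps <- diff(fit$history$loss)
  expect_gte(mean(steps < 0), 0.7)
})

test_that("checkpointing writes loadable best-loss weights", {
  set.seed(61)
  m <- build_model(tiny_model_config())
  ds <- make_tiny_set(4, seed = 3)
  ck <- tempfile(fileext = ".rds")
  fit <- train(m, ds, train_config(epochs = 2L, batch_size = 4L, seed = 1,
                                   checkpoint = ck))
  expect_true(file.exists(ck))
  m2 <- load_model(ck)
  expect_s3_class(m2, "lesionseg_model")
  unlink(ck)
})

test_that("non-finite inputs abort with a diagnostic", {
  set.seed(62)
  m <- build_model(tiny_model_config())
  bad <- make_tiny_set(2)
  bad[[1]]$image[1, 1, 1] <- NaN
  expect_error(train(m, bad, train_config(epochs = 1L, seed = 1)),
               "non-finite loss")
})

test_that("prediction thresholds behave at the extremes", {
  set.seed(70)
  m <- build_model(tiny_model_config())
  img <- rand_image(16, 16, 3, 4)
  # sigmoid output is strictly inside (0,1)
  expect_true(all(predict_masks(m, img, 0) == 1))
  expect_true(all(predict_masks(m, img, 1) == 0))
  p1 <- predict_masks(m, img, 0.5)
  p2 <- predict_masks(m, img, 0.5)
  expect_identical(p1, p2) # deterministic inference
  expect_true(all(p1 %in% c(0, 1)))
  # list input gives list output
  expect_length(predict_masks(m, list(img, img), 0.5), 2L)
})

test_that("evaluate wires predictions into averaged scores", {
  set.seed(71)
  m <- build_model(tiny_model_config())
  ds <- make_tiny_set(3, seed = 5)
  rep <- evaluate(m, ds, mode = "micro")
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$averaging_mode, "micro")
  expect_true(rep$dice >= 0 && rep$dice <= 1)
  expect_error(evaluate(m, list(list(image = ds[[1]]$image)), "none"),
               "masks")
})

test_that("contour overlay touches only boundary pixels", {
  img <- rand_image(20, 20, 3, 6)
  empty <- matrix(0, 20, 20)
  expect_identical(contour_overlay(img, empty), img)

  full <- matrix(1, 20, 20)
  ov <- contour_overlay(img, full)
  expect_equal(ov[1, 1, ], c(1, 0, 0))       # frame edge is boundary
  expect_equal(ov[10, 10, ], img[10, 10, ])  # interior untouched

  disk <- outer((1:20 - 10)^2, (1:20 - 10)^2, "+") <= 25
  ovd <- contour_overlay(img, disk * 1)
  changed <- which(apply(ovd != img, c(1, 2), any), arr.ind = TRUE)
  # every changed pixel is on the mask boundary (has a background 4-neighbour)
  for (r in seq_len(nrow(changed))) {
    i <- changed[r, 1]; j <- changed[r, 2]
    expect_true(disk[i, j])
    nb <- c(if (i > 1) disk[i - 1, j] else FALSE,
            if (i < 20) disk[i + 1, j] else FALSE,
            if (j > 1) disk[i, j - 1] else FALSE,
            if (j < 20) disk[i, j + 1] else FALSE)
    expect_true(any(!nb))
  }
})
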