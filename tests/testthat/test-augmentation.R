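toy_pair <- function(h = 12, w = 12, seed = 1) {
  set.seed(seed)
  list(image = array(runif(h * w * 3), c(h, w, 3)),
       mask = matrix(rbinom(h * w, 1, 0.3), h, w))
}

test_that("right-angle rotations: group laws and a hand-computed 3x3 case", {
  p <- toy_pair()
  r <- p
  for (i in 1:4) r <- rotate_pair(r$image, r$mask, 90)
  expect_identical(r$image, p$image)
  expect_identical(r$mask, p$mask)

  r180 <- rotate_pair(p$image, p$mask, 180)
  r90x2 <- rotate_pair(p$image, p$mask, 90)
  r90x2 <- rotate_pair(r90x2$image, r90x2$mask, 90)
  expect_identical(r180$image, r90x2$image)

  m <- matrix(as.numeric(1:9), 3, 3, byrow = TRUE)
  got <- rotate_pair(array(m / 10, c(3, 3, 1)), m, 90)$mask
  # counter-clockwise: first row becomes first column bottom-up
  expect_equal(got, matrix(c(3, 6, 9, 2, 5, 8, 1, 4, 7), 3, 3, byrow = TRUE))
  expect_error(rotate_pair(p$image, p$mask, 45), "angle")
})

test_that("crop_side removes the stated pixels then restores the frame", {
  p <- toy_pair(16, 256)
  expect_identical(crop_side(p$image, p$mask, "right", 0)$image, p$image)

  # gradient image: after cropping 90 from the right, the rightmost output
  # column must map to original column ~166 (= 256 - 90)
  grad <- array(rep(seq_len(256), each = 16) / 256, c(16, 256, 1))
  cr <- crop_side(grad, matrix(0, 16, 256), "right", 90)
  expect_equal(dim(cr$image), dim(grad))
  expect_equal(cr$image[1, 256, 1] * 256, 166, tolerance = 1)
  expect_equal(cr$image[1, 1, 1] * 256, 1, tolerance = 1)

  cl <- crop_side(grad, matrix(rbinom(16 * 256, 1, .5), 16, 256), "left", 90)
  expect_equal(cl$image[1, 1, 1] * 256, 91, tolerance = 1)
  expect_true(all(cl$mask %in% c(0, 1))) # nearest-neighbour keeps masks binary

  expect_error(crop_side(p$image, p$mask, "top", 16), "smaller")
})

test_that("flip and shift behave as enumerated", {
  p <- toy_pair()
  f2 <- flip_lr(p$image, p$mask)
  f2 <- flip_lr(f2$image, f2$mask)
  expect_identical(f2$image, p$image)

  tiny <- array(c(1, 3, 2, 4) / 4, c(2, 2, 1))
  fl <- flip_lr(tiny, matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(fl$image[, , 1], tiny[, 2:1, 1])

  imp <- matrix(0, 40, 40); imp[1, 1] <- 1
  sh <- shift_pair(array(imp, c(40, 40, 1)), imp, c(25, 25))
  expect_equal(which(sh$mask == 1, arr.ind = TRUE)[1, ], c(row = 26, col = 26))

  expect_identical(shift_pair(p$image, p$mask, c(0, 0))$mask, p$mask)

  # foreground loss equals pixels shifted out of frame
  m <- matrix(0, 30, 30); m[28:30, 28:30] <- 1
  sh2 <- shift_pair(array(0, c(30, 30, 1)), m, c(25, 25))
  kept <- sum(m[1:5, 1:5]) # pixels whose target stays in frame
  expect_equal(sum(sh2$mask), kept)
  expect_error(shift_pair(p$image, p$mask, c(50, 0)), "offset")
})

test_that("augment_sample: count, paired-transform fidelity, shapes", {
  p <- toy_pair(128, 128, 3)
  aug <- augment_sample(p$image, p$mask)
  expect_length(aug, 15L)
  expect_true(all(vapply(aug, function(a)
    identical(dim(a$image), dim(p$image)), logical(1))))
  expect_true(all(vapply(aug, function(a)
    all(a$mask %in% c(0, 1)), logical(1))))

  # replaying the recorded transform on the input mask reproduces the output
  replay <- function(label, mask) {
    parts <- strsplit(label, "_")[[1]]
    switch(parts[1],
           rotate = rotate_pair(array(mask, c(dim(mask), 1)), mask,
                                as.integer(parts[2]))$mask,
           crop = crop_side(array(mask, c(dim(mask), 1)), mask, parts[2],
                            as.integer(parts[3]))$mask,
           flip = flip_lr(array(mask, c(dim(mask), 1)), mask)$mask,
           shift = shift_pair(array(mask, c(dim(mask), 1)), mask,
                              as.integer(parts[2:3]))$mask)
  }
  for (a in aug) {
    expect_identical(a$mask, replay(a$transform, p$mask))
  }

  # the full registry including flip and shift has all 17 listed transforms
  aug17 <- augment_sample(p$image, p$mask,
                          augmentation_spec(include_flip = TRUE,
                                            include_shift = TRUE))
  expect_length(aug17, 17L)
  expect_true("flip_lr" %in% vapply(aug17, `[[`, "", "transform"))

  # determinism: same input, same spec, identical output
  aug2 <- augment_sample(p$image, p$mask)
  expect_identical(aug, aug2)
})
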