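test_that("confusion counting on enumerated toys", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)  # [[1,1],[0,0]] in row terms
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  c <- confusion_counts(matrix(c(1, 0, 1, 0), 2, 2),
                        matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(unlist(c[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))

  same <- matrix(rbinom(64, 1, .5), 8, 8)
  cs <- confusion_counts(same, same)
  expect_equal(cs$fp + cs$fn, 0)

  half <- matrix(rep(c(0, 1), each = 32), 8, 8)
  cc <- confusion_counts(1 - half, half)
  expect_equal(cc$tp + cc$tn, 0)

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the five scores match direct substitution, verbatim specificity", {
  c1 <- ns$counts_of(tp = 2, fp = 1, tn = 4, fn = 1)
  expect_equal(dice(c1), 2 / 3)
  expect_equal(jaccard(c1), 0.5)
  expect_equal(accuracy(c1), 0.75)
  expect_equal(sensitivity(c1), 2 / 3)
  expect_equal(specificity(c1), 2 / 3)  # TP/(TP+FP), as printed
  expect_equal(corrected_specificity(c1), 4 / 5)

  perfect <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  for (f in list(dice, jaccard, accuracy, sensitivity, specificity)) {
    expect_equal(f(perfect), 1)
  }
  disjoint <- ns$counts_of(tp = 0, fp = 3, tn = 0, fn = 3)
  expect_equal(dice(disjoint), 0)

  # degenerate both-empty convention
  empty <- confusion_counts(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(dice(empty), 1)
  expect_equal(dice(empty, empty_value = 0), 0)
})

test_that("dice-jaccard identity and ordering on random count tuples", {
  set.seed(10)
  for (i in 1:100) {
    c <- ns$counts_of(tp = rpois(1, 20), fp = rpois(1, 10), tn = rpois(1, 30),
                      fn = rpois(1, 10))
    d <- dice(c); j <- jaccard(c)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_gte(d, j)
    expect_true(d >= 0 && d <= 1 && j >= 0 && j <= 1)
  }
})

test_that("swapping pred and truth preserves dice/jaccard/accuracy only", {
  set.seed(3)
  a <- matrix(rbinom(100, 1, .4), 10, 10)
  b <- matrix(rbinom(100, 1, .5), 10, 10)
  cab <- confusion_counts(a, b); cba <- confusion_counts(b, a)
  expect_equal(dice(cab), dice(cba))
  expect_equal(jaccard(cab), jaccard(cba))
  expect_equal(accuracy(cab), accuracy(cba))
  expect_false(isTRUE(all.equal(sensitivity(cab), sensitivity(cba))))
})

test_that("averaging modes agree with brute-force pixel enumeration", {
  p1 <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  t1 <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  p2 <- matrix(c(0, 1, 1, 1, 0, 0, 0, 1, 0), 3, 3)
  t2 <- matrix(c(0, 1, 0, 1, 0, 0, 1, 1, 0), 3, 3)
  preds <- list(p1, p2); truths <- list(t1, t2)

  # enumeration oracle
  tally <- function(p, t) {
    c(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
      tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1))
  }
  e1 <- tally(p1, t1); e2 <- tally(p2, t2)
  d_of <- function(e) 2 * e["tp"] / (2 * e["tp"] + e["fp"] + e["fn"])

  none <- averaged_scores(preds, truths, "none")
  expect_equal(none$dice, unname((d_of(e1) + d_of(e2)) / 2))

  pool <- e1 + e2
  micro <- averaged_scores(preds, truths, "micro")
  expect_equal(micro$dice, unname(d_of(pool)))
  expect_equal(micro$accuracy, unname((pool["tp"] + pool["tn"]) / sum(pool)))

  macro <- averaged_scores(preds, truths, "macro")
  bg <- c(tp = unname(pool["tn"]), fp = unname(pool["fn"]),
          tn = unname(pool["tp"]), fn = unname(pool["fp"]))
  expect_equal(macro$dice, unname((d_of(pool) + d_of(bg)) / 2))

  # the three modes genuinely differ on this toy batch
  expect_length(unique(c(none$dice, micro$dice, macro$dice)), 3L)
})

test_that("averaging invariants: perfect batches, singletons, micro bounds", {
  m <- matrix(rbinom(64, 1, .4), 8, 8)
  for (mode in c("none", "micro", "macro")) {
    rep <- averaged_scores(list(m, m), list(m, m), mode)
    expect_equal(rep$dice, 1)
    expect_equal(rep$jaccard, 1)
    expect_equal(rep$averaging_mode, mode)
  }
  p <- matrix(rbinom(64, 1, .4), 8, 8)
  expect_equal(averaged_scores(list(p), list(m), "micro")$dice,
               averaged_scores(list(p), list(m), "none")$dice)

  set.seed(4)
  preds <- lapply(1:5, function(i) matrix(rbinom(64, 1, .4), 8, 8))
  truths <- lapply(1:5, function(i) matrix(rbinom(64, 1, .4), 8, 8))
  per <- per_image_scores(preds, truths)$dice
  mic <- averaged_scores(preds, truths, "micro")$dice
  expect_gte(mic, min(per))
  expect_lte(mic, max(per))
  expect_error(averaged_scores(list(), list(), "none"), "non-empty")
})
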