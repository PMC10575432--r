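# Confusion-matrix metrics.

test_that("accumulation is correct and associative", {
  cm <- confusion_matrix(2)
  pred <- matrix(0L, 2, 2); truth <- matrix(0L, 2, 2)
  cm <- cm_accumulate(cm, pred, truth)
  expect_equal(cm[1, 1], 4)

  # hand enumeration: truth (0,0,1,1), pred all 0 -> [[2,0],[2,0]]
  cm2 <- cm_accumulate(confusion_matrix(2), matrix(0L, 2, 2),
                       matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_equal(unclass(cm2), matrix(c(2L, 2L, 0L, 0L), 2, 2),
               ignore_attr = TRUE)

  # batch order never matters
  set.seed(41)
  preds <- lapply(1:4, function(i) matrix(sample(0:1, 16, TRUE), 4, 4))
  truths <- lapply(1:4, function(i) matrix(sample(0:1, 16, TRUE), 4, 4))
  acc <- function(ord) {
    cm <- confusion_matrix(2)
    for (i in ord) cm <- cm_accumulate(cm, preds[[i]], truths[[i]])
    cm
  }
  expect_equal(acc(1:4), acc(c(3, 1, 4, 2)))

  expect_error(cm_accumulate(confusion_matrix(2), matrix(2L, 2, 2),
                             matrix(0L, 2, 2)), "out of range")
  expect_error(cm_accumulate(confusion_matrix(2), matrix(0L, 2, 2),
                             matrix(0L, 2, 3)), "same shape")
})

test_that("miou, mpa and class accuracy follow their definitions", {
  # perfect prediction
  cmp <- matrix(c(10L, 0L, 0L, 6L), 2, 2)
  expect_equal(miou(cmp), 1)
  expect_equal(mpa(cmp), 1)
  expect_equal(class_accuracy(cmp, 0), 1)
  expect_equal(class_accuracy(cmp, 1), 1)

  # [[2,0],[2,0]]: IoU0 = 2/4, IoU1 = 0 -> miou 0.25; mpa = (1 + 0)/2
  cm <- matrix(c(2L, 2L, 0L, 0L), 2, 2)
  expect_equal(miou(cm), 0.25)
  expect_equal(mpa(cm), 0.5)
  expect_equal(class_accuracy(cm, 0), 1)
  expect_equal(class_accuracy(cm, 1), 0)

  # zero-union class is skipped, not counted as zero
  cm3 <- matrix(c(8L, 0L, 0L, 0L), 2, 2)  # no fish in truth or prediction
  expect_equal(miou(cm3), 1)
  expect_error(class_accuracy(cm3, 1), "no truth pixels")

  expect_error(miou(matrix(0L, 2, 2)), "all-zero")
})

test_that("metric bounds hold on random confusion matrices", {
  set.seed(42)
  for (rep in 1:50) {
    cm <- matrix(sample(0:30, 4, TRUE), 2, 2)
    if (sum(cm) == 0) next
    di <- diag(cm); un <- rowSums(cm) + colSums(cm) - di
    ious <- (di / un)[un > 0]
    m <- miou(cm)
    expect_gte(m, 0); expect_lte(m, 1)
    expect_lte(m, max(ious) + 1e-12)
    if (all(rowSums(cm) > 0)) {
      expect_gte(mpa(cm), 0); expect_lte(mpa(cm), 1)
    }
  }
})
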