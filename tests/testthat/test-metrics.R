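test_that("mask confusion counts match hand tallies", {
  t_ <- matrix(0, 20, 20); t_[1:10, 1:10] <- 1     # 100 foreground in 400
  cc <- confusionFromMasks(t_, t_)
  expect_identical(cc$tp, 100L + 0L); expect_identical(cc$tn, 300L)
  expect_identical(cc$fp, 0L); expect_identical(cc$fn, 0L)

  cc2 <- confusionFromMasks(1 - t_, t_)
  expect_identical(cc2$tp, 0L)
  expect_identical(cc2$fp + cc2$fn, 400L)

  # hand-drawn 4x4 example
  p <- matrix(c(1, 1, 0, 0,  0, 1, 0, 1,  0, 0, 0, 0,  1, 0, 0, 1), 4, 4)
  tr <- matrix(c(1, 0, 0, 0,  0, 1, 1, 1,  0, 0, 0, 0,  0, 0, 1, 1), 4, 4)
  cc3 <- confusionFromMasks(p, tr)
  expect_identical(cc3$tp, 4L); expect_identical(cc3$fp, 2L)
  expect_identical(cc3$fn, 2L); expect_identical(cc3$tn, 8L)

  expect_error(confusionFromMasks(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "spineDSS_validation_error")
})

test_that("ratio metrics follow their defining formulas and error on 0/0", {
  c1 <- confusionCounts(1, 1, 0, 0)
  expect_identical(c(specificity(c1), sensitivity(c1), precision(c1), accuracy(c1)),
                   rep(1, 4))
  c2 <- confusionCounts(94, 98, 2, 6)
  expect_equal(sensitivity(c2), 0.94)
  expect_equal(specificity(c2), 0.98)
  expect_error(precision(confusionCounts(0, 5, 0, 2)),
               class = "spineDSS_undefined_metric")
  expect_error(confusionCounts(-1, 0, 0, 0), class = "spineDSS_validation_error")
})

test_that("overlap coefficients satisfy their identities", {
  perfect <- confusionCounts(50, 10, 0, 0)
  expect_identical(dsc(perfect), 1); expect_identical(iou(perfect), 1)
  c3 <- confusionCounts(50, 0, 50, 50)
  expect_equal(iou(c3), 1 / 3)
  expect_equal(dsc(c3), 0.5)

  # a printed mean IoU of 90.4% implies a DSC of 95.0% at one decimal
  expect_equal(round(100 * 2 * 0.904 / (1 + 0.904), 1), 95.0)

  set.seed(41)
  for (rep in 1:10000) {
    cc <- confusionCounts(sample(0:50, 1) + 1, sample(0:50, 1),
                          sample(0:50, 1), sample(0:50, 1))
    d <- dsc(cc); i <- iou(cc)
    expect_lt(abs(d - 2 * i / (1 + i)), 1e-12)
    vals <- c(d, i, sensitivity(cc), accuracy(cc))
    expect_true(all(vals >= 0 & vals <= 1))
    tot <- cc$tp + cc$tn + cc$fp + cc$fn
    lhs <- accuracy(cc) * tot
    rhs <- sensitivity(cc) * (cc$tp + cc$fn) +
      (if (cc$fp + cc$tn > 0) specificity(cc) * (cc$fp + cc$tn) else 0)
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})

test_that("Fleiss' kappa matches hand computations and the random null", {
  expect_identical(fleissKappa(matrix(c(4, 0, 0, 4, 0, 0), 2, 3)), 1)
  expect_equal(fleissKappa(rbind(c(3, 0), c(1, 2))), 0.25)
  set.seed(42)
  big <- t(replicate(4000, tabulate(sample(1:4, 6, replace = TRUE), 4)))
  expect_lt(abs(fleissKappa(big)), 0.05)
  expect_lte(fleissKappa(big), 1)
  expect_error(fleissKappa(rbind(c(2, 1), c(1, 1))),
               class = "spineDSS_validation_error")
  expect_error(fleissKappa(rbind(c(1, 0))), class = "spineDSS_validation_error")
})

test_that("reader-study arithmetic reproduces relative improvements", {
  s <- readerStudySummary(
    data.frame(task = "diagnosis", accuracy = 61.67, time = 496.5),
    data.frame(task = "diagnosis", accuracy = 77.00, time = 321.8))
  expect_equal(s$perTask$accuracyImprovedPct, 24.86)
  expect_equal(s$perTask$timeReductionPct, 35.19)

  same <- readerStudySummary(
    data.frame(task = "x", accuracy = 50, time = 100),
    data.frame(task = "x", accuracy = 50, time = 100))
  expect_identical(same$perTask$accuracyImprovedPct, 0)
  expect_identical(same$perTask$timeReductionPct, 0)

  expect_error(readerStudySummary(
    data.frame(task = "a", accuracy = 1, time = 1),
    data.frame(task = "b", accuracy = 1, time = 1)),
    class = "spineDSS_validation_error")
})

test_that("one-vs-rest multiclass metrics mirror the per-grade table layout", {
  pred <- c(1, 2, 2, 3, 3, 3, 1, 2)
  truth <- c(1, 2, 3, 3, 3, 2, 1, 2)
  mm <- multiclassMetrics(pred, truth, classes = 1:3)
  expect_equal(mm$accuracy, 6 / 8)
  expect_equal(mm$perClass$precision[2], 2 / 3)
  expect_equal(mm$perClass$sensitivity[3], 2 / 3)
})
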