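# Segmentation metric suite against brute-force oracles and the
# hand-checked worked example TP=6, FP=2, FN=2, TN=90.

test_that("confusion counts match a per-pixel brute-force tally", {
  g <- squareMask(6L, 2, 4, 2, 4)
  cc <- confusionCounts(g, g)
  expect_equal(cc@TP, 9)
  expect_equal(cc@TN, 27)
  expect_equal(cc@FP + cc@FN, 0)

  z <- matrix(0L, 6, 6)
  cc0 <- confusionCounts(z, g)
  expect_equal(cc0@TP, 0)
  expect_equal(cc0@FN, 9)
  expect_equal(cc0@FP, 0)
  expect_equal(cc0@TN, 27)

  set.seed(4)
  for (i in 1:25) {
    p <- randomMask(8L); g <- randomMask(8L)
    cc <- confusionCounts(p, g)
    o <- bruteConfusion(p, g)
    expect_equal(c(TP = cc@TP, FP = cc@FP, FN = cc@FN, TN = cc@TN) + 0, o + 0)
  }
  expect_error(confusionCounts(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  expect_error(confusionCounts(matrix(2L, 2, 2), matrix(0L, 2, 2)), "labels")
})

test_that("accuracy metrics follow their defining ratios", {
  cc <- new("ConfusionCounts", TP = 6, FP = 2, FN = 2, TN = 90)
  a <- accuracyMetrics(cc)
  expect_equal(unname(a["globalAccuracy"]), 0.96)
  expect_equal(unname(a["meanAccuracy"]), (0.75 + 90 / 92) / 2)

  perfect <- accuracyMetrics(new("ConfusionCounts", TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(unname(perfect), c(1, 1))

  half <- accuracyMetrics(new("ConfusionCounts", TP = 0, FP = 0, FN = 50, TN = 50))
  expect_equal(unname(half), c(0.5, 0.5))

  noLesion <- accuracyMetrics(new("ConfusionCounts", TP = 0, FP = 1, FN = 0, TN = 9))
  expect_true(is.na(noLesion["meanAccuracy"]))
})

test_that("IoU family follows the per-class definitions and gold weights", {
  cc <- new("ConfusionCounts", TP = 6, FP = 2, FN = 2, TN = 90)
  m <- iouMetrics(cc)
  expect_equal(unname(m["iouLesion"]), 0.6)
  expect_equal(unname(m["iouBackground"]), 90 / 94)
  expect_equal(unname(m["meanIoU"]), (0.6 + 90 / 94) / 2)
  expect_equal(unname(m["lesionWeight"]), 0.08)
  expect_equal(unname(m["weightedIoU"]), 0.08 * 0.6 + 0.92 * 90 / 94)

  prf <- iouMetrics(new("ConfusionCounts", TP = 7, FP = 0, FN = 0, TN = 3))
  expect_equal(unname(prf[c("iouLesion", "iouBackground", "meanIoU", "weightedIoU")]),
               rep(1, 4))
})

test_that("dice matches its formula and its IoU identity", {
  expect_equal(diceCoefficient(new("ConfusionCounts", TP = 6, FP = 2, FN = 2, TN = 90)),
               0.75)
  expect_equal(diceCoefficient(new("ConfusionCounts", TP = 9, FP = 0, FN = 0, TN = 1)), 1)
  expect_equal(diceCoefficient(new("ConfusionCounts", TP = 0, FP = 4, FN = 4, TN = 2)), 0)
  expect_true(is.na(diceCoefficient(new("ConfusionCounts", TP = 0, FP = 0, FN = 0, TN = 9))))

  set.seed(8)
  for (i in 1:25) {
    p <- randomMask(16L); g <- randomMask(16L)
    cc <- confusionCounts(p, g)
    iou <- unname(iouMetrics(cc)["iouLesion"])
    expect_equal(diceCoefficient(cc), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("all ratio metrics agree with the brute-force oracle", {
  set.seed(21)
  for (i in 1:100) {
    p <- randomMask(16L, p = stats::runif(1, 0.1, 0.9))
    g <- randomMask(16L, p = stats::runif(1, 0.1, 0.9))
    cc <- confusionCounts(p, g)
    got <- c(unname(accuracyMetrics(cc)["globalAccuracy"]),
             unname(iouMetrics(cc)[c("iouLesion", "iouBackground", "meanIoU",
                                     "weightedIoU")]),
             diceCoefficient(cc))
    want <- bruteMetrics(p, g)
    keep <- !is.na(want) & !is.na(got)
    expect_lt(max(abs(got[keep] - want[keep])), 1e-12)
  }
})

test_that("label swap exchanges the class-wise metrics symmetrically", {
  set.seed(31)
  for (i in 1:20) {
    p <- randomMask(12L); g <- randomMask(12L)
    m1 <- iouMetrics(confusionCounts(p, g))
    m2 <- iouMetrics(confusionCounts(1L - p, 1L - g))
    expect_equal(unname(m1["iouLesion"]), unname(m2["iouBackground"]))
    expect_equal(unname(m1["lesionWeight"]), unname(m2["backgroundWeight"]))
    a1 <- accuracyMetrics(confusionCounts(p, g))
    a2 <- accuracyMetrics(confusionCounts(1L - p, 1L - g))
    expect_equal(a1[["globalAccuracy"]], a2[["globalAccuracy"]])
    if (!is.na(a1[["meanAccuracy"]]) && !is.na(a2[["meanAccuracy"]]))
      expect_equal(a1[["meanAccuracy"]], a2[["meanAccuracy"]])
  }
})

test_that("every metric stays inside [0, 1]", {
  set.seed(41)
  for (i in 1:30) {
    p <- randomMask(10L, stats::runif(1)); g <- randomMask(10L, stats::runif(1))
    r <- as.data.frame(segMetrics(p, g))
    v <- unlist(r)
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  }
})

test_that("correcting one false positive never hurts the headline metrics", {
  set.seed(51)
  for (i in 1:20) {
    p <- randomMask(10L, 0.5); g <- randomMask(10L, 0.5)
    fp <- which(p == 1L & g == 0L)
    if (!length(fp)) next
    p2 <- p
    p2[fp[1L]] <- 0L
    c1 <- confusionCounts(p, g); c2 <- confusionCounts(p2, g)
    expect_gte(accuracyMetrics(c2)[["globalAccuracy"]],
               accuracyMetrics(c1)[["globalAccuracy"]])
    expect_gte(iouMetrics(c2)[["iouLesion"]], iouMetrics(c1)[["iouLesion"]])
    expect_gte(diceCoefficient(c2), diceCoefficient(c1))
  }
})

test_that("boundary-F1 matches a brute-force matcher and degenerates safely", {
  g <- squareMask(16L, 5, 10, 5, 10)
  expect_equal(bfScore(g, g, 0L), 1)
  expect_equal(bfScore(g, g, 3L), 1)

  # shifted square beyond the tolerance, checked against the exhaustive oracle
  side <- 32L
  gold <- squareMask(side, 8, 15, 8, 15)
  for (tol in c(1L, 2L, 3L)) {
    pred <- squareMask(side, 8 + tol + 2L, 15 + tol + 2L, 8, 15)
    expect_equal(bfScore(pred, gold, tol), bruteBF(pred, gold, tol))
  }
  # random masks against the oracle
  set.seed(61)
  for (i in 1:5) {
    p <- randomMask(12L, 0.4); g2 <- randomMask(12L, 0.4)
    expect_equal(bfScore(p, g2, 2L), bruteBF(p, g2, 2L))
  }

  empty <- matrix(0L, 16L, 16L)
  expect_equal(bfScore(empty, g, 2L), 0)
  expect_true(is.na(bfScore(empty, empty, 2L)))
})

test_that("the default boundary tolerance follows the image diagonal", {
  expect_identical(bfTolerance(c(160L, 160L)), 2L)
  expect_identical(bfTolerance(c(320L, 320L)), 4L)
})

test_that("error overlay colours tally with the confusion counts", {
  set.seed(71)
  p <- randomMask(12L, 0.4); g <- randomMask(12L, 0.4)
  ov <- overlayErrors(p, g)
  cc <- confusionCounts(p, g)
  pink <- sum(ov[, , 1] == 1 & ov[, , 2] != 1)       # pink: R=1, G<1
  green <- sum(ov[, , 1] == 0 & ov[, , 2] == 1)
  white <- sum(ov[, , 1] == 1 & ov[, , 2] == 1 & ov[, , 3] == 1)
  expect_equal(pink, cc@FP)
  expect_equal(green, cc@FN)
  expect_equal(white, cc@TP)

  same <- overlayErrors(g, g)
  expect_equal(sum(same[, , 2] == 1 & same[, , 1] == 0), 0)  # no green
  allLesion <- matrix(1L, 4, 4); allBg <- matrix(0L, 4, 4)
  ovp <- overlayErrors(allLesion, allBg)
  expect_true(all(ovp[, , 1] == 1 & ovp[, , 2] < 1))         # all pink
})

test_that("set evaluation averages per image and skips flagged values", {
  g1 <- squareMask(16L, 4, 8, 4, 8)
  p1 <- squareMask(16L, 5, 9, 4, 8)
  one <- evaluateSet(list(list(pred = p1, gold = g1)))
  r1 <- as.data.frame(segMetrics(p1, g1))
  expect_equal(one$summary$mean[one$summary$metric == "dice"], r1$dice)
  expect_true(all(is.na(one$summary$sd)))

  two <- evaluateSet(list(list(pred = p1, gold = g1), list(pred = p1, gold = g1)))
  expect_true(all(two$summary$sd[two$summary$n == 2] == 0))

  p2 <- squareMask(16L, 4, 8, 5, 9); p3 <- g1
  three <- evaluateSet(list(list(pred = p1, gold = g1),
                            list(pred = p2, gold = g1),
                            list(pred = p3, gold = g1)))
  hand <- mean(c(as.data.frame(segMetrics(p1, g1))$dice,
                 as.data.frame(segMetrics(p2, g1))$dice,
                 as.data.frame(segMetrics(p3, g1))$dice))
  expect_equal(three$summary$mean[three$summary$metric == "dice"], hand)

  expect_error(evaluateSet(list()), "non-empty")
})
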