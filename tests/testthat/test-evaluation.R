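fixture4x4 <- function() {
  gold <- matrix(FALSE, 4, 4)
  gold[1, 1] <- gold[2, 2] <- gold[3, 3] <- TRUE     # 3 vessel pixels
  pred <- matrix(FALSE, 4, 4)
  pred[1, 1] <- pred[2, 2] <- TRUE                   # hits 2
  pred[4, 4] <- TRUE                                 # adds 1
  list(pred = pred, gold = gold)
}

test_that("confusion counts match hand counts and identities", {
  f <- fixture4x4()
  cc <- confusionCounts(f$pred, f$gold)
  expect_equal(cc, c(TP = 2L, FP = 1L, TN = 12L, FN = 1L)[names(cc)])
  expect_equal(sum(cc), 16)

  g <- f$gold
  same <- confusionCounts(g, g)
  expect_equal(same[["FP"]], 0L)
  expect_equal(same[["FN"]], 0L)
  inv <- confusionCounts(!g, g)
  expect_equal(inv[["TP"]], 0L)
  expect_equal(inv[["TN"]], 0L)
  expect_error(confusionCounts(g, matrix(FALSE, 3, 4)), "shape")
})

test_that("confusion is symmetric under joint complement", {
  set.seed(51)
  pred <- matrix(runif(100) > 0.5, 10)
  gold <- matrix(runif(100) > 0.5, 10)
  a <- confusionCounts(pred, gold)
  b <- confusionCounts(!pred, !gold)
  expect_equal(a[["TP"]], b[["TN"]])
  expect_equal(a[["FP"]], b[["FN"]])
})

test_that("metrics follow the standard formulas", {
  m <- segMetrics(c(TP = 50, FP = 10, TN = 930, FN = 10))
  expect_equal(m[["sensitivity"]], 50 / 60)
  expect_equal(m[["specificity"]], 930 / 940)
  expect_equal(m[["accuracy"]], 0.98)

  f <- fixture4x4()
  perfect <- segMetrics(confusionCounts(f$gold, f$gold))
  expect_equal(unname(perfect), c(1, 1, 1))

  expect_equal(segMetrics(c(TP = 0, FP = 5, TN = 10, FN = 5))[["sensitivity"]], 0)

  # the TN-only accuracy variant scores a perfect segmentation below 1
  asPrinted <- segMetrics(confusionCounts(f$gold, f$gold),
                          accuracyAsPrinted = TRUE)
  expect_equal(asPrinted[["accuracy"]], 13 / 16)

  expect_warning(segMetrics(c(TP = 0, FP = 0, TN = 10, FN = 0)), "sensitivity")
})

test_that("overlay classes are coloured as TP green, FP blue, FN red", {
  f <- fixture4x4()
  ov <- overlayMask(f$pred, f$gold)
  isCol <- function(col) sum(ov[, , 1] == col[1] & ov[, , 2] == col[2] &
                             ov[, , 3] == col[3])
  expect_equal(isCol(c(0, 1, 0)), 2)  # TP
  expect_equal(isCol(c(0, 0, 1)), 1)  # FP
  expect_equal(isCol(c(1, 0, 0)), 1)  # FN

  # overlay class counts equal the confusion counts on random masks
  set.seed(52)
  pred <- matrix(runif(400) > 0.5, 20)
  gold <- matrix(runif(400) > 0.5, 20)
  cc <- confusionCounts(pred, gold)
  ov2 <- overlayMask(pred, gold)
  expect_equal(sum(ov2[, , 2] == 1 & ov2[, , 1] == 0 & ov2[, , 3] == 0),
               cc[["TP"]])
  expect_equal(sum(ov2[, , 3] == 1 & ov2[, , 1] == 0 & ov2[, , 2] == 0),
               cc[["FP"]])
  expect_equal(sum(ov2[, , 1] == 1 & ov2[, , 2] == 0 & ov2[, , 3] == 0),
               cc[["FN"]])

  # identical masks: only green and background
  ovs <- overlayMask(f$gold, f$gold)
  expect_equal(sum(ovs[, , 3] == 1), 0)
  expect_equal(sum(ovs[, , 1] == 1), 0)
  # empty prediction: only red and background
  ovr <- overlayMask(matrix(FALSE, 4, 4), f$gold)
  expect_equal(sum(ovr[, , 1] == 1), 3)
  expect_equal(sum(ovr[, , 2] == 1), 0)
})

test_that("dual-gold reports compare both references and regenerate identically", {
  f <- fixture4x4()
  r <- dualGoldReport(f$pred, f$gold, f$gold)
  expect_equal(r[1, -1], r[2, -1], ignore_attr = TRUE)

  gold1 <- f$gold
  gold2 <- f$gold; gold2[4, 4] <- TRUE          # superset; pred == gold2
  r2 <- dualGoldReport(gold2, gold1, gold2)
  expect_gt(r2$FP[1], 0)
  expect_equal(r2$FP[2], 0)

  ph <- testPhantom(seed = 14)
  pred <- ph$truth; pred[5, 5] <- TRUE
  a <- dualGoldReport(pred, ph$truth, fov = ph$fov, widthMap = ph$widthMap)
  b <- dualGoldReport(pred, ph$truth, fov = ph$fov, widthMap = ph$widthMap)
  expect_identical(a, b)
  expect_true(any(grepl("small", a$gold)))
})

test_that("small-vessel sensitivity counts recovered thin-vessel pixels", {
  ph <- testPhantom(seed = 15)
  small <- ph$truth & ph$widthMap > 0 & ph$widthMap <= 2
  expect_equal(smallVesselSensitivity(ph$truth, small, ph$fov), 1)
  expect_equal(smallVesselSensitivity(!ph$truth, small, ph$fov), 0)
  expect_true(is.nan(smallVesselSensitivity(ph$truth, matrix(FALSE, 192, 192),
                                            ph$fov)))
})
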