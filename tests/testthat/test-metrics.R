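# losses and the six-metric evaluation suite

test_that("dice loss: perfect, disjoint, half-overlap", {
  m <- matrix(0, 8, 8); m[2:3, 2:3] <- 1
  expect_lt(dice_loss(m, m), 0.12)          # eps-limited
  expect_equal(dice_loss(m, m, eps = 1e-9), 0, tolerance = 1e-6)
  d <- matrix(0, 8, 8); d[6:7, 6:7] <- 1
  expect_equal(dice_loss(d, m, eps = 1e-9), 1, tolerance = 1e-6)
  # pred support 2px, truth 2px, overlap 1px -> 1 - 2*1/(2+2) = 0.5
  p <- matrix(0, 4, 4); p[1, 1:2] <- 1
  y <- matrix(0, 4, 4); y[1:2, 1] <- 1
  expect_equal(dice_loss(p, y, eps = 0), 0.5)
})

test_that("cross-entropy loss: closed forms", {
  y <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(ce_loss(matrix(0.5, 2, 2), y), log(2), tolerance = 1e-12)
  expect_equal(ce_loss(matrix(1, 1, 1), matrix(1, 1, 1)), 0, tolerance = 1e-6)
  expect_equal(ce_loss(matrix(0.25, 1, 1), matrix(1, 1, 1)), log(4),
               tolerance = 1e-12)
})

test_that("composite loss is the weighted sum of its parts", {
  set.seed(41)
  p <- matrix(runif(36), 6, 6)
  y <- rand_mask(6, 6)
  expect_equal(composite_loss(p, y), dice_loss(p, y) + ce_loss(p, y))
  base_ce <- ce_loss(p, y)
  expect_equal(composite_loss(p, y, w_ce = 2) - composite_loss(p, y),
               base_ce, tolerance = 1e-12)
  expect_lt(composite_loss(y, y, dice_eps = 1e-9), 1e-5)
})

test_that("confusion counts partition the pixel grid", {
  set.seed(42)
  y <- rand_mask(10, 10)
  cc <- confusion_counts(y, y)
  expect_equal(cc$TP, sum(y)); expect_equal(cc$TN, 100 - sum(y))
  expect_equal(cc$FP + cc$FN, 0)
  cc2 <- confusion_counts(1 - y, y)
  expect_equal(cc2$TP + cc2$TN, 0)
  for (i in 1:10) {
    a <- rand_mask(8, 12); b <- rand_mask(8, 12)
    cc3 <- confusion_counts(a, b)
    expect_equal(cc3$TP + cc3$TN + cc3$FP + cc3$FN, 96)
  }
})

test_that("dsc and iou: worked 4x4 example and duality", {
  # pred 6 px, truth 4 px, overlap 3 px -> dsc 60, iou 3/7
  p <- matrix(0, 4, 4); p[1, ] <- 1; p[2, 1:2] <- 1
  y <- matrix(0, 4, 4); y[1, 1:3] <- 1; y[3, 4] <- 1
  expect_equal(sum(p), 6); expect_equal(sum(y), 4); expect_equal(sum(p * y), 3)
  expect_equal(dsc(p, y), 60)
  expect_equal(iou(p, y), 100 * 3 / 7, tolerance = 1e-10)
  expect_equal(dsc(p, y), 200 * iou(p, y) / (100 + iou(p, y)), tolerance = 1e-10)
  expect_equal(dsc(y, y), 100)
  expect_equal(iou(p, matrix(0, 4, 4)), 0)
  expect_equal(dsc(matrix(0, 4, 4), matrix(0, 4, 4)), 100) # both-empty
  # duality and symmetry across random pairs
  set.seed(43)
  for (i in 1:25) {
    a <- rand_blob_mask(16, 16); b <- rand_blob_mask(16, 16)
    expect_equal(dsc(a, b), 200 * iou(a, b) / (100 + iou(a, b)),
                 tolerance = 1e-9)
    expect_equal(dsc(a, b), dsc(b, a))
    expect_equal(iou(a, b), iou(b, a))
  }
})

test_that("hd95: singletons, identity, oracle, and percentile bound", {
  a <- matrix(0, 9, 9); a[5, 2] <- 1
  b <- matrix(0, 9, 9); b[5, 7] <- 1
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(a, b, percentile = 10), 5) # singleton sets, any percentile
  expect_equal(hd95(b, b), 0)
  expect_true(is.na(hd95(a, matrix(0, 9, 9))))
  set.seed(44)
  for (i in 1:20) {
    p <- rand_blob_mask(24, 24); q <- rand_blob_mask(24, 24)
    if (sum(p) == 0 || sum(q) == 0) next
    expect_equal(hd95(p, q), oracle_hd(p, q), tolerance = 1e-9)
    expect_equal(hd95(p, q), hd95(q, p))
    expect_lte(hd95(p, q), hd95(p, q, percentile = 100) + 1e-12)
    expect_equal(hd95(p, q, percentile = 100), oracle_hd(p, q, 100),
                 tolerance = 1e-9)
  }
})

test_that("accuracy, kappa, mcc: worked example and conventions", {
  cc <- structure(list(TP = 40, TN = 40, FP = 10, FN = 10),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 80)
  expect_equal(kappa(cc), 60)
  expect_equal(mcc(cc), 60)
  y <- rand_mask(10, 10, 0.4)
  ccp <- confusion_counts(y, y)
  expect_equal(kappa(ccp), 100)
  expect_equal(mcc(ccp), 100)
  # all-one predictions vs half-one truth: chance level, kappa = 0
  y2 <- matrix(rep(c(0, 1), 50), 10, 10)
  cc2 <- confusion_counts(matrix(1, 10, 10), y2)
  expect_equal(kappa(cc2), 0)
  # mcc denominator zero -> 0 by convention (degenerate margins)
  cc0 <- confusion_counts(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_equal(mcc(cc0), 0)
  cc00 <- confusion_counts(matrix(0, 4, 4), matrix(1, 4, 4))
  expect_equal(mcc(cc00), 0)
  # kappa/mcc symmetric under pred/truth transposition of a binary table
  set.seed(45)
  for (i in 1:10) {
    a <- rand_mask(12, 12); b <- rand_mask(12, 12)
    expect_equal(kappa(confusion_counts(a, b)), kappa(confusion_counts(b, a)),
                 tolerance = 1e-12)
    expect_equal(mcc(confusion_counts(a, b)), mcc(confusion_counts(b, a)),
                 tolerance = 1e-12)
    expect_equal(accuracy(confusion_counts(a, b)),
                 accuracy(confusion_counts(b, a)))
  }
})

test_that("mcc equals kappa on balanced margins", {
  cc <- structure(list(TP = 30, TN = 30, FP = 20, FN = 20),
                  class = "confusion_counts")
  expect_equal(mcc(cc), kappa(cc))
  cc2 <- structure(list(TP = 45, TN = 15, FP = 20, FN = 20),
                   class = "confusion_counts")
  expect_equal(mcc(cc2), kappa(cc2), tolerance = 1e-12)
})

test_that("dataset evaluation aggregates with the chosen sd and writes CSV", {
  p1 <- matrix(0, 4, 4); p1[1, ] <- 1; p1[2, 1:2] <- 1
  y1 <- matrix(0, 4, 4); y1[1, 1:3] <- 1; y1[3, 4] <- 1   # dsc 60
  y2 <- rand_mask(4, 4, 0.5)
  pairs <- list(list(pred = p1, truth = y1, id = "a"),
                list(pred = y2, truth = y2, id = "b"))   # dsc 100
  rep <- evaluate_dataset(pairs)
  expect_equal(rep$per_image$dsc, c(60, 100))
  expect_equal(rep$summary$mean[rep$summary$metric == "dsc"], 80)
  expect_equal(rep$summary$sd[rep$summary$metric == "dsc"], sd(c(60, 100)))
  repp <- evaluate_dataset(pairs, sd_type = "population")
  expect_equal(repp$summary$sd[repp$summary$metric == "dsc"], 20)
  # all-perfect: mean 100, sd 0
  perf <- evaluate_dataset(list(list(pred = y2, truth = y2, id = "x"),
                                list(pred = p1, truth = p1, id = "y")))
  expect_equal(perf$summary$mean[perf$summary$metric == "dsc"], 100)
  expect_equal(perf$summary$sd[perf$summary$metric == "dsc"], 0)
  # CSV: image count + 1 summary row
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, tmp)
  got <- read.csv(tmp)
  expect_equal(nrow(got), 3)
  expect_equal(got$id[3], "mean")
  # undefined hd95 excluded with count
  pairs_na <- c(pairs, list(list(pred = matrix(0, 4, 4), truth = y1, id = "c")))
  rep_na <- evaluate_dataset(pairs_na)
  expect_equal(rep_na$hd95_excluded, 1)
  expect_false(is.na(rep_na$summary$mean[rep_na$summary$metric == "hd95"]))
})
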