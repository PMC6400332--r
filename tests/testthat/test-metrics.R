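test_that("confusion counts match the exhaustive per-pixel tally", {
  set.seed(21)
  for (rep in 1:5) {
    pred <- random_mask(8, 8); gt <- random_mask(8, 8)
    cc <- confusion_counts(pred, gt)
    expect_identical(cc, oracle_confusion(pred, gt))
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 64L)
  }
})

test_that("perfect and empty predictions give the expected counts", {
  gt <- matrix(0L, 10, 10); gt[1, 1:10] <- 1L
  cc <- confusion_counts(gt, gt)
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(10L, 90L, 0L, 0L))
  cc0 <- confusion_counts(matrix(0L, 10, 10), gt)
  expect_equal(c(cc0$FN, cc0$TN), c(10L, 90L))
})

test_that("TPR and TNR are the stated ratios with undefined-degenerate flags", {
  expect_equal(tpr(list(TP = 8, FN = 2, TN = 0, FP = 0)), 0.8)
  expect_equal(tnr(list(TN = 99, FP = 1, TP = 0, FN = 0)), 0.99)
  expect_true(is.na(tpr(list(TP = 0, FN = 0, TN = 5, FP = 5))))
  expect_true(is.na(tnr(list(TN = 0, FP = 0, TP = 5, FN = 5))))
})

test_that("DSC handles identity, disjoint and partial overlap", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  expect_equal(dsc(a, a), 1)
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  expect_equal(dsc(a, b), 0)
  gt <- matrix(0L, 6, 6); gt[1, 1:4] <- 1L       # |gt| = 4
  pr <- matrix(0L, 6, 6); pr[1, 2:6] <- 1L; pr[2, 1] <- 1L  # |pred| = 6, overlap 3
  expect_equal(dsc(pr, gt), 0.6)
  expect_true(is.na(dsc(matrix(0L, 3, 3), matrix(0L, 3, 3))))
  expect_error(dsc(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               class = "suvseg_format_error")
})

test_that("DSC equals 2TP/(2TP+FP+FN) on random masks", {
  set.seed(22)
  for (rep in 1:10) {
    pred <- random_mask(12, 12); gt <- random_mask(12, 12)
    cc <- confusion_counts(pred, gt)
    expect_equal(dsc(pred, gt), 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
  }
})

test_that("directed Hausdorff reproduces the 3-4-5 triangle and identity", {
  A <- matrix(c(0, 0), 1); B <- matrix(c(3, 4), 1)
  expect_equal(directed_hausdorff(A, B), 5)
  expect_equal(hausdorff(A, B), 5)
  P <- matrix(c(1, 2, 5, 7, 2, 2), ncol = 2)
  expect_equal(hausdorff(P, P), 0)
})

test_that("Hausdorff matches the exhaustive max-min oracle on random sets", {
  set.seed(23)
  for (rep in 1:5) {
    A <- matrix(sample(0:40, 60, replace = TRUE), ncol = 2)
    B <- matrix(sample(0:40, 60, replace = TRUE), ncol = 2)
    expect_identical(directed_hausdorff(A, B), oracle_directed_hd(A, B))
    expect_identical(hausdorff(A, B), oracle_hd(A, B))
  }
})

test_that("directed Hausdorff is asymmetric, the symmetric form is not", {
  A <- matrix(c(0, 0), 1)
  B <- matrix(c(0, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(directed_hausdorff(A, B), 0)
  expect_equal(directed_hausdorff(B, A), 10)
  expect_equal(hausdorff(A, B), hausdorff(B, A))
})

test_that("Hausdorff is translation invariant and scales linearly", {
  set.seed(24)
  A <- matrix(sample(0:20, 30, replace = TRUE), ncol = 2)
  B <- matrix(sample(0:20, 30, replace = TRUE), ncol = 2)
  h <- hausdorff(A, B)
  expect_equal(hausdorff(A + 7, B + 7), h)
  expect_equal(hausdorff(A * 3, B * 3), 3 * h)
})

test_that("one far outlier moves HD a lot but DSC by O(1/area)", {
  gt <- matrix(0L, 64, 64); gt[20:40, 20:40] <- 1L
  pred <- gt
  h0 <- mask_hausdorff(pred, gt); d0 <- dsc(pred, gt)
  pred[64, 64] <- 1L
  h1 <- mask_hausdorff(pred, gt); d1 <- dsc(pred, gt)
  expect_gt(h1 - h0, 20)
  expect_lt(d0 - d1, 2 / sum(gt))
})

test_that("empty masks give undefined Hausdorff", {
  expect_true(is.na(mask_hausdorff(matrix(0L, 4, 4), random_mask(4, 4, 0.5))))
})

test_that("cohort evaluation averages per-pair metrics, excluding undefined", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  rep <- evaluate_cohort(list(list(pred = a, gt = a), list(pred = b, gt = a)))
  expect_equal(unname(rep$means["dsc"]), 0.5)
  one <- evaluate_cohort(list(list(pred = a, gt = a)))
  expect_equal(unname(one$means["dsc"]), 1)
  expect_equal(nrow(one$per_pair), 1L)
})

test_that("cohort means equal composed per-pair oracle values", {
  set.seed(25)
  pairs <- lapply(1:20, function(i) list(pred = random_mask(10, 10),
                                         gt = random_mask(10, 10)))
  rep <- suppressMessages(evaluate_cohort(pairs))
  o_dsc <- vapply(pairs, function(p) oracle_dsc(p$pred, p$gt), 0)
  o_hd <- vapply(pairs, function(p) {
    A <- which(p$pred != 0, arr.ind = TRUE); B <- which(p$gt != 0, arr.ind = TRUE)
    if (nrow(A) == 0 || nrow(B) == 0) NA_real_ else oracle_hd(A, B)
  }, 0)
  expect_equal(unname(rep$means["dsc"]), mean(o_dsc, na.rm = TRUE))
  expect_equal(unname(rep$means["hd"]), mean(o_hd, na.rm = TRUE))
})
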