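test_that("F1 reproduces the published precision/recall summaries", {
  # printed P/R are themselves rounded to 3 d.p., so recomputed F1 can be off
  # by one unit in the last place (0.8046 vs printed 0.804)
  expect_lt(abs(f1_score(0.865, 0.752) - 0.804), 1e-3)
  expect_lt(abs(f1_score(0.783, 0.638) - 0.703), 1e-3)
  expect_equal(f1_score(0.6, 0.6), 0.6)       # harmonic-mean fixed point
  expect_equal(f1_score(0, 0), 0)
  set.seed(2)
  for (i in 1:30) {
    P <- runif(1, 0.01, 1); R <- runif(1, 0.01, 1)
    f <- f1_score(P, R)
    expect_gte(f, min(P, R)); expect_lte(f, max(P, R))
  }
  expect_error(f1_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("detection matching is greedy, one-to-one, by confidence", {
  gt <- list(rect_mask(10, 10, 10, 10))
  # two predictions over one ground truth: IoUs 0.6.., 0.5..
  p1 <- rect_mask(10, 12, 10, 10, confidence = 0.9)   # IoU 8/12 = 0.667
  p2 <- rect_mask(10, 13, 10, 10, confidence = 0.8)   # IoU 7/13 = 0.538
  mm <- match_detections(list(p1, p2), gt, 0.4)
  expect_equal(mm$TP, 1); expect_equal(mm$FP, 1); expect_equal(mm$FN, 0)
  expect_equal(mm$pairs$pred, 1)

  perfect <- match_detections(gt, gt, 0.4)
  expect_equal(c(perfect$TP, perfect$FP, perfect$FN), c(1, 0, 0))
  none <- match_detections(list(), gt, 0.4)
  expect_equal(c(none$TP, none$FP, none$FN), c(0, 0, 1))
})

test_that("PR sweep finds the P = R operating point", {
  gt <- list(list(rect_mask(10, 10, 5, 5), rect_mask(50, 50, 5, 5)))
  perfect <- list(list(rect_mask(10, 10, 5, 5, confidence = 0.9),
                       rect_mask(50, 50, 5, 5, confidence = 0.8)))
  res <- pr_curve_f1(perfect, gt)
  expect_equal(res$f1, 1)
  expect_true(all(res$curve$P == 1))
  expect_equal(res$curve$R[res$curve$threshold == 0.8], 1)  # all detections in

  # 5 gt; detector: 4 hits at high conf + 1 false alarm at higher conf =>
  # at the all-in threshold P = R = 0.8 exactly
  gt2 <- list(lapply(seq(0, 80, 20), function(u) rect_mask(u, 10, 5, 5)))
  preds2 <- list(c(lapply(seq(0, 60, 20), function(u)
    rect_mask(u, 10, 5, 5, confidence = 0.9)),
    list(rect_mask(50, 100, 5, 5, confidence = 0.95))))
  res2 <- pr_curve_f1(preds2, gt2)
  expect_equal(res2$f1, 0.8)

  # the curve equals an independent brute-force threshold sweep
  set.seed(14)
  gt3 <- list(lapply(seq(0, 90, 15), function(u) rect_mask(u, 10, 6, 6)))
  preds3 <- list(lapply(seq(0, 90, 15), function(u) {
    if (runif(1) < 0.3) rect_mask(u + 40, 150, 6, 6, confidence = runif(1))
    else rect_mask(u, 10 + sample(0:2, 1), 6, 6, confidence = runif(1))
  }))
  res3 <- pr_curve_f1(preds3, gt3)
  for (r in seq_len(nrow(res3$curve))) {
    thr <- res3$curve$threshold[r]
    kept <- Filter(function(m) m$confidence >= thr, preds3[[1]])
    mm <- match_detections(kept, gt3[[1]], 0.4)
    P <- if (mm$TP + mm$FP == 0) 1 else mm$TP / (mm$TP + mm$FP)
    R <- mm$TP / (mm$TP + mm$FN)
    expect_equal(res3$curve$P[r], P)
    expect_equal(res3$curve$R[r], R)
  }
})

test_that("segmentation IoU handles the canonical cases", {
  a <- rect_mask(0, 0, 10, 10)
  expect_equal(segmentation_iou(a, a), 1)
  expect_equal(segmentation_iou(a, rect_mask(10, 0, 10, 10)), 0)
  # half-overlapping equal squares: intersection A/2, union 3A/2
  expect_equal(segmentation_iou(a, rect_mask(5, 0, 10, 10)), 1 / 3)
})

test_that("instance vs semantic protocols on a constructed error case", {
  # 10x10 image; gt: two 2x2 squares; pred: one exact match + one false alarm
  gt <- list(rect_mask(0, 0, 2, 2, sub_class = "SB"),
             rect_mask(5, 5, 2, 2, sub_class = "Th"))
  pred <- list(rect_mask(0, 0, 2, 2, sub_class = "SB", confidence = 0.9),
               rect_mask(8, 0, 2, 2, sub_class = "SB", confidence = 0.8))
  ev <- instance_vs_semantic_eval(pred, gt, 10, 10)
  expect_equal(ev$instance$fg_iou, 1 / 3)            # mean(1, 0, 0)
  expect_equal(ev$instance$fg_iou_matched, 1)
  expect_equal(ev$instance$bg_iou, mean(c(1, 0.96, 0.96)))
  expect_equal(ev$semantic$fg_iou, 1 / 3)            # 4 / 12
  expect_equal(ev$semantic$bg_iou, 88 / 96)
  expect_equal(ev$semantic$mu_iou, (1 / 3 + 88 / 96) / 2)

  perfect <- instance_vs_semantic_eval(gt, gt, 10, 10)
  expect_equal(perfect$instance$fg_iou, 1)
  expect_equal(perfect$semantic$mu_iou, 1)
})

test_that("semantic FG IoU dominates instance-averaged FG IoU under errors", {
  # the Table-4-style gap arises when matched instances segment well but
  # small false alarms and small missed objects each contribute a zero to the
  # instance average while barely moving the pooled pixel mass
  set.seed(31)
  for (i in 1:10) {
    n_big <- sample(3:6, 1)
    gt <- lapply(seq_len(n_big), function(k)
      rect_mask(10 + 30 * (k - 1), 10, 16, 16))
    pred <- lapply(gt, function(m)
      instance_mask(m$pixels, confidence = runif(1, 0.5, 1)))
    # small missed objects (FN) and small false alarms (FP)
    for (k in seq_len(sample(1:3, 1)))
      gt <- c(gt, list(rect_mask(sample(10:180, 1), 60, 4, 4)))
    for (k in seq_len(sample(1:3, 1)))
      pred <- c(pred, list(rect_mask(sample(10:180, 1), 90, 4, 4,
                                     confidence = runif(1, 0.5, 1))))
    ev <- instance_vs_semantic_eval(pred, gt, 200, 120)
    expect_gt(ev$semantic$fg_iou, ev$instance$fg_iou)
  }
})

test_that("confusion accuracy is the mean diagonal of a normalized matrix", {
  expect_equal(confusion_accuracy(diag(4)), 1)
  expect_equal(confusion_accuracy(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)), 0.85)
  I <- 5
  expect_equal(confusion_accuracy(matrix(1 / I, I, I)), 1 / I)
  expect_error(confusion_accuracy(matrix(c(0.9, 0.3, 0.1, 0.8), 2, 2)),
               "normalized")

  # invariant under simultaneous row/column permutation
  C <- matrix(c(0.7, 0.1, 0.3, 0.2, 0.8, 0.1, 0.1, 0.1, 0.6), 3, 3)
  p <- c(3, 1, 2)
  expect_equal(confusion_accuracy(C[p, p]), confusion_accuracy(C))
})

test_that("confusion matrices count IoU-matched pairs only", {
  vocab <- c("SB", "Th")
  gt <- list(rect_mask(0, 0, 4, 4, sub_class = "SB"),
             rect_mask(20, 0, 4, 4, sub_class = "Th"))
  pred <- list(rect_mask(0, 0, 4, 4, sub_class = "Th", confidence = 0.9),
               rect_mask(40, 40, 4, 4, sub_class = "SB", confidence = 0.8))
  C <- confusion_matrix(pred, gt, vocab)
  expect_equal(C["SB", "Th"], 1)        # matched pair, label confused
  expect_equal(sum(C["Th", ]), 0)       # unmatched gt contributes nothing
})

test_that("mu-NAE matches hand arithmetic and its invariances", {
  expect_equal(mu_nae(c(5, 9), c(5, 9)), 0)
  expect_equal(mu_nae(c(100, 200), c(90, 210)), 0.075)
  expect_equal(mu_nae(c(10, 20), c(20, 40)), 1)     # unbounded above
  expect_equal(mu_nae(c(10, 20), c(9, 18)), mu_nae(c(30, 60), c(27, 54)))
  expect_error(mu_nae(c(0, 5), c(1, 5)), "positive")
  expect_warning(v <- mu_nae(c(0, 5), c(1, 5), per_subclass = TRUE), "excluded")
  expect_equal(v, 0)
})

test_that("R^2 agrees with the closed-form OLS oracle", {
  gt <- c(10, 20, 40)
  expect_equal(r_squared(gt, gt), 1)
  expect_equal(r_squared(gt, 3 * gt + 7), 1)        # any exact linear model
  pred <- c(12, 19, 44)
  # closed form: Sxy^2 / (Sxx * Syy)
  sxx <- sum((gt - mean(gt))^2); syy <- sum((pred - mean(pred))^2)
  sxy <- sum((gt - mean(gt)) * (pred - mean(pred)))
  expect_equal(r_squared(gt, pred), sxy^2 / (sxx * syy))
  # identity-line convention penalizes offsets the fitted one forgives
  expect_equal(r_squared(gt, gt + 5, method = "identity"),
               1 - 3 * 25 / sxx)
  expect_error(r_squared(c(5, 5), c(4, 6)), "non-constant")
})

test_that("row-count tables validate their totals", {
  df <- data.frame(row = c("R1", "R3"), SB = c(120, 93), Ch = c(16, 45),
                   total = c(136, 138))
  p <- withr::local_tempfile(fileext = ".csv")
  write_row_counts(df, p)
  expect_equal(read_row_counts(p)$total, c(136, 138))
  bad <- df; bad$total <- c(10, 10)
  expect_error(write_row_counts(bad, p), "totals")
})
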