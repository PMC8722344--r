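#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`; defined as 0 when both are 0.
#' @param P,R Precision and recall in `[0, 1]`.
#' @export
f1_score <- function(P, R) {
  if (any(c(P, R) < 0) || any(c(P, R) > 1)) stop("P and R must be in [0, 1]")
  ifelse(P + R == 0, 0, 2 * P * R / (P + R))
}

#' Match predicted to ground-truth masks within one frame
#'
#' Greedy matching by descending prediction confidence: each prediction
#' claims the unclaimed ground-truth mask of maximal IoU provided that IoU
#' reaches `iou_threshold` (the evaluation protocol uses 0.4). Unmatched
#' predictions are false positives, unmatched ground truths false negatives.
#'
#' @param predictions,ground_truth Lists of [instance_mask()].
#' @param iou_threshold Minimum IoU for a valid match.
#' @return List with `TP`, `FP`, `FN` and `pairs`
#'   (data frame: pred, gt, iou).
#' @export
match_detections <- function(predictions, ground_truth, iou_threshold = 0.4) {
  conf <- vapply(predictions, function(m) m$confidence, numeric(1))
  ord <- order(-conf, seq_along(predictions))
  claimed <- rep(FALSE, length(ground_truth))
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  for (p in ord) {
    if (!length(ground_truth)) break
    ious <- vapply(seq_along(ground_truth), function(g)
      if (claimed[g]) -1 else iou_affinity(predictions[[p]], ground_truth[[g]]),
      numeric(1))
    g <- which.max(ious)
    if (ious[g] >= iou_threshold) {
      claimed[g] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = p, gt = g, iou = ious[g]))
    }
  }
  list(TP = nrow(pairs), FP = length(predictions) - nrow(pairs),
       FN = length(ground_truth) - nrow(pairs), pairs = pairs)
}

#' Precision-recall curve and F1 at the P = R operating point
#'
#' Sweeps confidence thresholds over the scored predictions of one or more
#' frames, matching at each threshold, and reports the curve plus the F1
#' evaluated where precision equals recall (linearly interpolated between the
#' adjacent operating points when the crossing falls between samples).
#'
#' @param predictions List (per frame) of lists of scored [instance_mask()].
#' @param ground_truth List (per frame) of lists of [instance_mask()].
#' @param iou_threshold IoU needed for a true positive.
#' @return List with `curve` (data frame: threshold, P, R, F1) and `f1`
#'   (F1 at the P = R point).
#' @export
pr_curve_f1 <- function(predictions, ground_truth, iou_threshold = 0.4) {
  stopifnot(length(predictions) == length(ground_truth))
  confs <- sort(unique(unlist(lapply(predictions, function(fr)
    vapply(fr, function(m) m$confidence, numeric(1))))))
  if (!length(confs)) stop("no scored predictions")
  curve <- do.call(rbind, lapply(confs, function(thr) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(predictions)) {
      kept <- Filter(function(m) m$confidence >= thr, predictions[[i]])
      mm <- match_detections(kept, ground_truth[[i]], iou_threshold)
      tp <- tp + mm$TP; fp <- fp + mm$FP; fn <- fn + mm$FN
    }
    P <- if (tp + fp == 0) 1 else tp / (tp + fp)
    R <- if (tp + fn == 0) 1 else tp / (tp + fn)
    data.frame(threshold = thr, P = P, R = R, F1 = f1_score(P, R))
  }))
  diff <- curve$P - curve$R
  if (nrow(curve) == 1L || all(diff >= 0) || all(diff <= 0)) {
    f1 <- curve$F1[which.min(abs(diff))]
  } else {
    k <- which(diff[-nrow(curve)] * diff[-1L] <= 0)[1L]
    w <- if (diff[k + 1L] == diff[k]) 0 else diff[k] / (diff[k] - diff[k + 1L])
    P <- curve$P[k] + w * (curve$P[k + 1L] - curve$P[k])
    R <- curve$R[k] + w * (curve$R[k + 1L] - curve$R[k])
    f1 <- f1_score(P, R)
  }
  list(curve = curve, f1 = f1)
}

#' Pixel-wise IoU of two masks
#'
#' @param output_mask,gt_mask [instance_mask()] objects.
#' @export
segmentation_iou <- function(output_mask, gt_mask) {
  iou_affinity(output_mask, gt_mask)
}

union_keys <- function(masks) {
  unique(unlist(lapply(masks, function(m) pix_key(m$pixels))))
}

#' Instance vs. semantic segmentation evaluation
#'
#' Instance protocol: predictions and ground truths are matched at
#' `iou_threshold`; the foreground IoU is averaged over the union of
#' instances, with false positives and missed detections contributing 0, and
#' the background IoU is the complement-mask IoU averaged the same way.
#' The `fg_iou_matched` variant restricts to matched pairs only. Semantic
#' protocol: all instances on each side collapse to one binary map and
#' FG/BG IoU are computed pixel-wise. `mu_iou = (bg + fg) / 2` in both.
#'
#' @param predictions,ground_truth Lists of [instance_mask()] for one frame
#'   (or pre-pooled across frames).
#' @param width,height Image size in pixels.
#' @param iou_threshold Match threshold for the instance protocol.
#' @return Nested list with `$instance` (`bg_iou`, `fg_iou`,
#'   `fg_iou_matched`, `mu_iou`) and `$semantic` (`bg_iou`, `fg_iou`,
#'   `mu_iou`).
#' @export
instance_vs_semantic_eval <- function(predictions, ground_truth, width, height,
                                      iou_threshold = 0.4) {
  n_px <- as.numeric(width) * height
  mm <- match_detections(predictions, ground_truth, iou_threshold)
  fg <- bg <- numeric(0)
  if (nrow(mm$pairs)) {
    fg <- mm$pairs$iou
    bg <- vapply(seq_len(nrow(mm$pairs)), function(k) {
      a <- pix_key(predictions[[mm$pairs$pred[k]]]$pixels)
      b <- pix_key(ground_truth[[mm$pairs$gt[k]]]$pixels)
      inter <- sum(a %in% b)
      # complement IoU: |A' & B'| / |A' | B'| on the full pixel grid
      (n_px - (length(a) + length(b) - inter)) / (n_px - inter)
    }, numeric(1))
  }
  fp_idx <- setdiff(seq_along(predictions), mm$pairs$pred)
  fn_idx <- setdiff(seq_along(ground_truth), mm$pairs$gt)
  for (i in fp_idx) {
    n <- nrow(predictions[[i]]$pixels)
    fg <- c(fg, 0); bg <- c(bg, (n_px - n) / n_px)
  }
  for (i in fn_idx) {
    n <- nrow(ground_truth[[i]]$pixels)
    fg <- c(fg, 0); bg <- c(bg, (n_px - n) / n_px)
  }
  inst <- list(bg_iou = if (length(bg)) mean(bg) else 1,
               fg_iou = if (length(fg)) mean(fg) else 1,
               fg_iou_matched = if (nrow(mm$pairs)) mean(mm$pairs$iou) else NA_real_)
  inst$mu_iou <- (inst$bg_iou + inst$fg_iou) / 2

  kp <- union_keys(predictions); kg <- union_keys(ground_truth)
  inter <- sum(kp %in% kg)
  uni <- length(kp) + length(kg) - inter
  fg_sem <- if (uni == 0) 1 else inter / uni
  bg_inter <- n_px - uni
  bg_uni <- n_px - inter
  sem <- list(bg_iou = if (bg_uni == 0) 1 else bg_inter / bg_uni,
              fg_iou = fg_sem)
  sem$mu_iou <- (sem$bg_iou + sem$fg_iou) / 2
  list(instance = inst, semantic = sem)
}

#' Row-normalized sub-class confusion matrix from matched pairs
#'
#' Only IoU-matched prediction/ground-truth pairs enter the matrix (the
#' protocol excludes false and missed detections, which inflates apparent
#' accuracy — interpret together with detection metrics).
#'
#' @param predictions,ground_truth Lists of [instance_mask()] (one frame or
#'   pooled).
#' @param vocab Sub-class vocabulary giving row/column order.
#' @param iou_threshold Match threshold.
#' @return I x I matrix, rows = ground truth, each nonzero row summing to 1.
#' @export
confusion_matrix <- function(predictions, ground_truth, vocab,
                             iou_threshold = 0.4) {
  vocab <- subclass_vocabulary(vocab)
  C <- matrix(0, length(vocab), length(vocab),
              dimnames = list(gt = vocab, pred = vocab))
  mm <- match_detections(predictions, ground_truth, iou_threshold)
  if (nrow(mm$pairs)) for (k in seq_len(nrow(mm$pairs))) {
    g <- ground_truth[[mm$pairs$gt[k]]]$sub_class
    p <- predictions[[mm$pairs$pred[k]]]$sub_class
    if (!is.na(g) && !is.na(p)) C[g, p] <- C[g, p] + 1
  }
  rs <- rowSums(C)
  C[rs > 0, ] <- C[rs > 0, , drop = FALSE] / rs[rs > 0]
  C
}

#' Average accuracy of a normalized confusion matrix
#'
#' Mean of the diagonal entries of a row-normalized I x I confusion matrix.
#' @param C Row-normalized square confusion matrix.
#' @export
confusion_accuracy <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
  rs <- rowSums(C)
  if (any(rs > 0 & abs(rs - 1) > 1e-9))
    stop("confusion matrix rows must be normalized (or all-zero)")
  mean(diag(C))
}

#' Mean normalized absolute count error
#'
#' `mean(|GT_i - P_i| / GT_i)` over rows: 0 is perfect and the metric is
#' unbounded above (predictions above twice the ground truth exceed 1).
#'
#' @param gt,pred Numeric vectors of ground-truth and predicted counts per
#'   row.
#' @param per_subclass Set `TRUE` when scoring individual sub-classes: rows
#'   with `GT = 0` are then excluded with a warning instead of erroring.
#' @export
mu_nae <- function(gt, pred, per_subclass = FALSE) {
  stopifnot(length(gt) == length(pred))
  zero <- gt == 0
  if (any(zero)) {
    if (!per_subclass) stop("ground-truth counts must be positive")
    warning(sprintf("%d row(s) with zero ground truth excluded", sum(zero)))
    gt <- gt[!zero]; pred <- pred[!zero]
  }
  mean(abs(gt - pred) / gt)
}

#' Coefficient of determination for count agreement
#'
#' By default the R^2 of the ordinary least-squares fit of predictions on
#' ground truth (`method = "fitted"`); `method = "identity"` instead scores
#' residuals from the 1:1 line.
#'
#' @param gt,pred Numeric count vectors (at least 2 rows, non-constant `gt`).
#' @param method `"fitted"` or `"identity"`.
#' @export
r_squared <- function(gt, pred, method = c("fitted", "identity")) {
  method <- match.arg(method)
  if (length(gt) < 2L || stats::var(gt) == 0)
    stop("R^2 needs at least two rows with non-constant ground truth")
  ss_tot <- sum((pred - mean(pred))^2)
  if (method == "fitted") {
    if (ss_tot == 0) return(1)  # constant predictions fit themselves exactly
    fit <- stats::lm(pred ~ gt)
    1 - sum(stats::residuals(fit)^2) / ss_tot
  } else {
    ss_tot_gt <- sum((gt - mean(gt))^2)
    1 - sum((pred - gt)^2) / ss_tot_gt
  }
}

#' Read / write visual ground-truth count tables
#'
#' CSV with a `row` id column, one column per sub-class, and a `total`
#' column; the validator checks `total` equals the row sum.
#'
#' @param path CSV file path.
#' @return Data frame of counts.
#' @export
read_row_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cls <- setdiff(names(df), c("row", "total"))
  if (!all(df$total == rowSums(df[, cls, drop = FALSE])))
    stop("row totals do not equal the sum of sub-class counts")
  df
}

#' @rdname read_row_counts
#' @param df Data frame with `row`, per-sub-class columns, `total`.
#' @export
write_row_counts <- function(df, path) {
  cls <- setdiff(names(df), c("row", "total"))
  if (!all(df$total == rowSums(df[, cls, drop = FALSE])))
    stop("row totals do not equal the sum of sub-class counts")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
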