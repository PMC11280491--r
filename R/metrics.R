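# Evaluation metrics: Dice similarity coefficient, 95th-percentile Hausdorff
# distance, IoU, accuracy, Cohen's kappa and Matthews correlation — reported
# in percent (HD95 in pixels), matching the conventions of segmentation
# challenge leaderboards.

as_binary_mask <- function(x, threshold = 0.5) {
  x <- vals(x)
  if (length(dim(x)) == 3 && dim(x)[1] == 1) x <- x[1, , ]
  (x > threshold) * 1L
}

#' Confusion-matrix counts for a binary mask pair
#'
#' Probabilities are thresholded at 0.5 before counting.
#'
#' @param pred predicted mask or probability map.
#' @param truth ground-truth binary mask.
#' @param threshold binarisation threshold for probabilistic input.
#' @return object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion_counts <- function(pred, truth, threshold = 0.5) {
  p <- as_binary_mask(pred, threshold)
  y <- as_binary_mask(truth, threshold)
  stopifnot(identical(dim(p), dim(y)))
  tp <- sum(p == 1 & y == 1)
  tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn), class = "confusion_counts")
}

#' Dice similarity coefficient (percent)
#'
#' `200 * |X intersect Y| / (|X| + |Y|)` for the foreground class; two empty
#' masks score 100 by convention.
#'
#' @inheritParams confusion_counts
#' @return percent in `[0, 100]`.
#' @export
dsc <- function(pred, truth) {
  p <- as_binary_mask(pred); y <- as_binary_mask(truth)
  denom <- sum(p) + sum(y)
  if (denom == 0) return(100)
  200 * sum(p * y) / denom
}

#' Intersection over union (percent)
#'
#' @inheritParams confusion_counts
#' @return percent in `[0, 100]`; two empty masks score 100.
#' @export
iou <- function(pred, truth) {
  p <- as_binary_mask(pred); y <- as_binary_mask(truth)
  un <- sum(p | y)
  if (un == 0) return(100)
  100 * sum(p & y) / un
}

# 8-connected boundary: foreground pixels with at least one background pixel
# (or the image border) among their 8 neighbours.
mask_boundary <- function(mask) {
  m <- as_binary_mask(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- matrix(1L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    inner <- inner & pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  m == 1L & !inner
}

#' 95th-percentile Hausdorff distance (pixels)
#'
#' Boundary pixels of the two masks are extracted (8-connectivity, image
#' border counts as background); both directed nearest-neighbour Euclidean
#' distance sets are pooled and the 95th percentile (linear interpolation)
#' returned. `percentile = 100` gives the exact Hausdorff distance. If
#' either mask is empty the distance is undefined and `NA` is returned.
#'
#' @inheritParams confusion_counts
#' @param percentile percentile of the pooled distance set (default 95).
#' @return distance in pixels, or `NA_real_` if undefined.
#' @export
hd95 <- function(pred, truth, percentile = 95) {
  p <- as_binary_mask(pred); y <- as_binary_mask(truth)
  stopifnot(identical(dim(p), dim(y)))
  if (sum(p) == 0 || sum(y) == 0) return(NA_real_)
  bp <- mask_boundary(p); by <- mask_boundary(y)
  dist_to_y <- cpp_edt(by)
  dist_to_p <- cpp_edt(bp)
  pooled <- c(dist_to_y[bp], dist_to_p[by])
  as.numeric(quantile(pooled, percentile / 100, type = 7, names = FALSE))
}

#' Accuracy, Cohen's kappa and Matthews correlation from confusion counts
#'
#' `accuracy` is the fraction of correctly classified pixels; `kappa`
#' corrects observed agreement for chance agreement computed from the
#' marginals; `mcc` is the correlation over all four confusion cells (0 by
#' convention when its denominator vanishes). All reported in percent.
#'
#' @param counts a [confusion_counts()] object (or a mask pair via
#'   `confusion_counts` first).
#' @return percent; kappa and mcc lie in `[-100, 100]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  100 * (counts$TP + counts$TN) / tot
}

#' @rdname accuracy
#' @export
kappa <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  tot <- tp + tn + fp + fn
  po <- (tp + tn) / tot
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / tot^2
  if (abs(1 - pe) < 1e-12) return(100 * (po >= 1 - 1e-12))
  100 * (po - pe) / (1 - pe)
}

#' @rdname accuracy
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(0)
  100 * (tp * tn - fp * fn) / den
}

#' Evaluate a set of prediction/ground-truth pairs
#'
#' Computes the six metrics per image and aggregates mean and standard
#' deviation; images with undefined HD95 (an empty mask on either side) are
#' excluded from the HD95 aggregate and counted.
#'
#' @param pairs list of `list(pred=, truth=, id=)` mask pairs.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return list with `$per_image` (data.frame), `$summary` (mean/sd per
#'   metric), `$hd95_excluded` (count of undefined HD95 images).
#' @export
evaluate_dataset <- function(pairs, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(pairs) > 0)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    cc <- confusion_counts(pr$pred, pr$truth)
    data.frame(id = pr$id %||% as.character(i),
               dsc = dsc(pr$pred, pr$truth),
               hd95 = hd95(pr$pred, pr$truth),
               iou = iou(pr$pred, pr$truth),
               accuracy = accuracy(cc), kappa = kappa(cc), mcc = mcc(cc))
  })
  per <- do.call(rbind, rows)
  sdev <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1) return(0)
    if (sd_type == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  }
  metrics <- c("dsc", "hd95", "iou", "accuracy", "kappa", "mcc")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) sdev(per[[m]]), 0))
  list(per_image = per, summary = summary,
       hd95_excluded = sum(is.na(per$hd95)))
}

#' Write a metric report as CSV
#'
#' One row per image plus a final summary row (`id = "mean"`).
#'
#' @param report result of [evaluate_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  per <- report$per_image
  mean_row <- data.frame(id = "mean", t(report$summary$mean))
  names(mean_row) <- names(per)
  write.csv(rbind(per, mean_row), path, row.names = FALSE)
  invisible(path)
}
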