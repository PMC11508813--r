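#' Match predicted wheal clusters against expected ones
#'
#' Greedy one-to-one matching by descending pixel-overlap IoU; a pair can
#' match only if its IoU is strictly positive. Unmatched predicted clusters
#' are type I errors (detections of non-existing wheals); unmatched expected
#' clusters are type II errors (missed wheals).
#'
#' @param predicted,expected lists of clusters from [cluster_pixels()] on
#'   same-size masks.
#' @return a `detection_outcome` list: `matched_pairs` (two-column matrix of
#'   predicted / expected ids), `correct_detection`, `expected_detection`,
#'   `type1_errors`, `type2_errors`, `iou` (IoU per matched pair).
#' @export
match_detections <- function(predicted, expected) {
  np <- length(predicted)
  ne <- length(expected)
  enc <- function(px) (px[, 1] - 1) * 2^26 + px[, 2]  # unique pixel keys
  iou <- matrix(0, np, ne)
  if (np > 0 && ne > 0) {
    pk <- lapply(predicted, function(cl) enc(cl$pixels))
    ek <- lapply(expected, function(cl) enc(cl$pixels))
    for (i in seq_len(np)) {
      for (j in seq_len(ne)) {
        inter <- sum(pk[[i]] %in% ek[[j]])
        if (inter > 0) {
          iou[i, j] <- inter / (length(pk[[i]]) + length(ek[[j]]) - inter)
        }
      }
    }
  }
  pairs <- matrix(integer(), 0, 2,
                  dimnames = list(NULL, c("predicted", "expected")))
  pair_iou <- numeric()
  m <- iou
  while (any(m > 0)) {
    best <- which(m == max(m), arr.ind = TRUE)[1, , drop = TRUE]
    pairs <- rbind(pairs, c(predicted[[best[1]]]$id, expected[[best[2]]]$id))
    pair_iou <- c(pair_iou, m[best[1], best[2]])
    m[best[1], ] <- 0
    m[, best[2]] <- 0
  }
  structure(
    list(
      matched_pairs = pairs,
      iou = pair_iou,
      correct_detection = nrow(pairs),
      expected_detection = ne,
      type1_errors = np - nrow(pairs),
      type2_errors = ne - nrow(pairs)
    ),
    class = "detection_outcome"
  )
}

#' Detection accuracy
#'
#' The detection score used to summarize wheal finding:
#' `100 * correct / (expected + type I errors)`, where type I errors are
#' detections of non-existing wheals.
#'
#' @param outcome a `detection_outcome` from [match_detections()], or a
#'   correct-detection count when `expected` and `type1` are given.
#' @param expected,type1 counts (used when `outcome` is a plain count).
#' @return percentage in `[0, 100]`.
#' @export
detection_accuracy <- function(outcome, expected = NULL, type1 = NULL) {
  if (inherits(outcome, "detection_outcome")) {
    correct <- outcome$correct_detection
    expected <- outcome$expected_detection
    type1 <- outcome$type1_errors
  } else {
    correct <- outcome
  }
  den <- expected + type1
  if (den <= 0) stop_input("detection accuracy undefined: zero denominator")
  100 * correct / den
}

#' Per-wheal confusion-matrix metrics
#'
#' Scores one matched predicted/expected wheal pair inside a local
#' evaluation window: the bounding box of the union of the two clusters'
#' pixels, dilated by `pad_px` and clipped to the image. Within the window,
#' TP/FP/FN/TN are counted on the wheal class of the full masks. Note that
#' only accuracy and specificity depend on the window size (extra
#' true-negative pixels); sensitivity, DSC and IoU do not.
#'
#' @param predicted_mask,expected_mask [label_mask()]s of equal size.
#' @param predicted_cluster,expected_cluster the matched clusters.
#' @param pad_px window dilation margin, default 5.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   `dsc`, `iou` (0..1), the window, and the confusion counts.
#' @export
cluster_confusion_metrics <- function(predicted_mask, expected_mask,
                                      predicted_cluster, expected_cluster,
                                      pad_px = 5) {
  if (!all(dim(predicted_mask) == dim(expected_mask))) {
    stop_input("mask dimensions differ")
  }
  px <- rbind(predicted_cluster$pixels, expected_cluster$pixels)
  r0 <- max(1L, min(px[, 1]) - pad_px)
  r1 <- min(nrow(predicted_mask), max(px[, 1]) + pad_px)
  c0 <- max(1L, min(px[, 2]) - pad_px)
  c1 <- min(ncol(predicted_mask), max(px[, 2]) + pad_px)
  p <- unclass(predicted_mask)[r0:r1, c0:c1] == 1L
  e <- unclass(expected_mask)[r0:r1, c0:c1] == 1L
  tp <- sum(p & e)
  fp <- sum(p & !e)
  fn <- sum(!p & e)
  tn <- sum(!p & !e)
  total <- tp + fp + fn + tn
  if (total == 0) stop_input("empty evaluation window")
  list(
    accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    dsc = 2 * tp / (2 * tp + fp + fn),
    iou = tp / (tp + fp + fn),
    window = c(row0 = r0, row1 = r1, col0 = c0, col1 = c1),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
    pad_px = pad_px
  )
}

#' Evaluate a predicted mask against a reference mask
#'
#' Full scoring pass: clusters both masks, matches detections, computes
#' detection accuracy and per-matched-wheal confusion metrics, and
#' macro-averages (unweighted mean across wheals).
#'
#' @param predicted_mask,expected_mask [label_mask()]s.
#' @param min_size cluster size filter.
#' @param pad_px evaluation window margin.
#' @return list with `detection` (the outcome), `detection_accuracy`,
#'   `per_wheal` (data frame), and `means`.
#' @export
evaluate_masks <- function(predicted_mask, expected_mask, min_size = 10,
                           pad_px = 5) {
  pred <- cluster_pixels(predicted_mask, "wheal", min_size)
  expd <- cluster_pixels(expected_mask, "wheal", min_size)
  outcome <- match_detections(pred, expd)
  per <- lapply(seq_len(nrow(outcome$matched_pairs)), function(k) {
    pid <- outcome$matched_pairs[k, 1]
    eid <- outcome$matched_pairs[k, 2]
    m <- cluster_confusion_metrics(
      predicted_mask, expected_mask,
      pred[[pid]], expd[[eid]], pad_px = pad_px
    )
    data.frame(
      predicted_id = pid, expected_id = eid,
      accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, dsc = m$dsc, iou = m$iou
    )
  })
  per <- if (length(per)) {
    do.call(rbind, per)
  } else {
    data.frame(
      predicted_id = integer(), expected_id = integer(),
      accuracy = numeric(), sensitivity = numeric(),
      specificity = numeric(), dsc = numeric(), iou = numeric()
    )
  }
  means <- if (nrow(per)) {
    colMeans(per[, c("accuracy", "sensitivity", "specificity", "dsc", "iou")])
  } else {
    c(accuracy = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
      dsc = NA_real_, iou = NA_real_)
  }
  list(
    detection = outcome,
    detection_accuracy = if (outcome$expected_detection +
                               outcome$type1_errors > 0) {
      detection_accuracy(outcome)
    } else {
      NA_real_
    },
    per_wheal = per,
    means = as.list(means),
    pad_px = pad_px
  )
}
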