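mask_from_regions <- function(h, w, regions) {
  g <- matrix(0L, h, w)
  for (r in regions) g[r$rows, r$cols] <- 1L
  label_mask(g)
}

test_that("match_detections handles identity, misses and false alarms", {
  truth <- mask_from_regions(60, 60, list(
    list(rows = 5:15, cols = 5:15),
    list(rows = 30:45, cols = 20:40)
  ))
  pred_same <- cluster_pixels(truth, "wheal")
  expd <- cluster_pixels(truth, "wheal")
  out <- match_detections(pred_same, expd)
  expect_equal(out$correct_detection, 2)
  expect_equal(out$type1_errors, 0)
  expect_equal(out$type2_errors, 0)
  expect_equal(out$iou, c(1, 1))

  # one extra disjoint prediction: a type I error
  pred_extra <- mask_from_regions(60, 60, list(
    list(rows = 5:15, cols = 5:15),
    list(rows = 30:45, cols = 20:40),
    list(rows = 50:55, cols = 50:55)
  ))
  out2 <- match_detections(cluster_pixels(pred_extra, "wheal"), expd)
  expect_equal(out2$correct_detection, 2)
  expect_equal(out2$type1_errors, 1)
  # invariants of the outcome
  expect_equal(out2$correct_detection + out2$type2_errors,
               out2$expected_detection)

  # a missed wheal: type II
  pred_miss <- mask_from_regions(60, 60, list(list(rows = 5:15, cols = 5:15)))
  out3 <- match_detections(cluster_pixels(pred_miss, "wheal"), expd)
  expect_equal(out3$type2_errors, 1)
})

test_that("greedy IoU matching equals exhaustive assignment on small cases", {
  set.seed(51)
  for (i in 1:6) {
    truth <- matrix(FALSE, 40, 40)
    n <- sample(2:4, 1)
    for (k in seq_len(n)) {
      r0 <- 2 + 9 * (k - 1) + sample(0:2, 1)
      truth[r0:(r0 + 6), sample(3:30, 1) + 0:6] <- TRUE
    }
    # prediction: truth shifted by one pixel, one blob sometimes dropped
    pred <- truth
    pred <- rbind(pred[-1, ], FALSE)
    expd <- cluster_pixels(label_mask(matrix(as.integer(truth), 40, 40)),
                           "wheal", min_size = 1)
    prd <- cluster_pixels(label_mask(matrix(as.integer(pred), 40, 40)),
                          "wheal", min_size = 1)
    out <- match_detections(prd, expd)
    iou <- matrix(0, length(prd), length(expd))
    for (a in seq_along(prd)) {
      for (b in seq_along(expd)) {
        ka <- (prd[[a]]$pixels[, 1] - 1) * 64 + prd[[a]]$pixels[, 2]
        kb <- (expd[[b]]$pixels[, 1] - 1) * 64 + expd[[b]]$pixels[, 2]
        inter <- sum(ka %in% kb)
        if (inter > 0) iou[a, b] <- inter / (length(ka) + length(kb) - inter)
      }
    }
    best <- oracle_best_matching(iou)
    expect_equal(out$correct_detection, nrow(best$pairs))
    expect_equal(sum(out$iou), best$score, tolerance = 1e-12)
  }
})

test_that("detection accuracy implements the correct/expected+typeI ratio", {
  expect_equal(round(detection_accuracy(144, 150, 3), 2), 94.12)
  expect_equal(detection_accuracy(150, 150, 0), 100)
  expect_equal(detection_accuracy(0, 150, 0), 0)
  expect_error(detection_accuracy(0, 0, 0), "zero denominator")
  # monotonicity: more type I errors always lower the score
  accs <- vapply(0:5, function(t1) detection_accuracy(140, 150, t1), 0)
  expect_true(all(diff(accs) < 0))
})

test_that("cluster confusion metrics match closed forms", {
  truth <- mask_from_regions(40, 40, list(list(rows = 11:20, cols = 11:20)))
  expd <- cluster_pixels(truth, "wheal")[[1]]

  # identity
  m <- cluster_confusion_metrics(truth, truth, expd, expd)
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$dsc, 1)
  expect_equal(m$iou, 1)

  # predicted covers the left half, no false positives
  half <- mask_from_regions(40, 40, list(list(rows = 11:20, cols = 11:15)))
  prd <- cluster_pixels(half, "wheal")[[1]]
  m2 <- cluster_confusion_metrics(half, truth, prd, expd)
  expect_equal(m2$sensitivity, 50)
  expect_equal(m2$dsc, 2 / 3)
  expect_equal(m2$iou, 1 / 2)
  expect_equal(m2$specificity, 100)

  # sensitivity/DSC/IoU do not depend on the window padding
  m3 <- cluster_confusion_metrics(half, truth, prd, expd, pad_px = 12)
  expect_equal(m3$sensitivity, m2$sensitivity)
  expect_equal(m3$dsc, m2$dsc)
  expect_equal(m3$iou, m2$iou)
  expect_gt(m3$accuracy, m2$accuracy)  # extra TN-only pixels dilute errors
})

test_that("DSC equals 2 IoU / (1 + IoU) on random mask pairs", {
  set.seed(77)
  for (i in 1:8) {
    # one random blob and a shifted copy: overlapping single-cluster masks,
    # so full-mask set operations are an independent oracle for the
    # windowed confusion counts
    a <- matrix(FALSE, 50, 50)
    a[sample(10:35, 1) + 0:sample(4:8, 1),
      sample(10:35, 1) + 0:sample(4:8, 1)] <- TRUE
    shift <- sample(-2:2, 2, replace = TRUE)
    idx <- which(a, arr.ind = TRUE)
    b <- matrix(FALSE, 50, 50)
    b[cbind(idx[, 1] + shift[1], idx[, 2] + shift[2])] <- TRUE
    ma <- label_mask(matrix(as.integer(a), 50, 50))
    mb <- label_mask(matrix(as.integer(b), 50, 50))
    ca <- cluster_pixels(ma, "wheal", min_size = 1)[[1]]
    cb <- cluster_pixels(mb, "wheal", min_size = 1)[[1]]
    m <- cluster_confusion_metrics(ma, mb, ca, cb)
    # independent set-operation computation of DSC and IoU
    iou_ind <- sum(a & b) / sum(a | b)
    dsc_ind <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(m$iou, iou_ind, tolerance = 1e-12)
    expect_equal(m$dsc, dsc_ind, tolerance = 1e-12)
    expect_equal(m$dsc, 2 * iou_ind / (1 + iou_ind), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under simultaneous mirroring", {
  truth <- mask_from_regions(30, 30, list(list(rows = 5:14, cols = 8:17)))
  pred <- mask_from_regions(30, 30, list(list(rows = 6:15, cols = 8:17)))
  ev1 <- evaluate_masks(pred, truth, min_size = 1)
  img <- array(0, c(30, 30, 3))
  pred_m <- augment_mirror(img, pred)[[3]]$mask
  truth_m <- augment_mirror(img, truth)[[3]]$mask
  ev2 <- evaluate_masks(pred_m, truth_m, min_size = 1)
  expect_equal(ev1$means, ev2$means)
  expect_equal(ev1$detection_accuracy, ev2$detection_accuracy)
})
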