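test_that("semantic IoU counts pixels and handles the empty case", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(as.numeric(semanticIoU(a, a)), 1)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(as.numeric(semanticIoU(a, b)), 0)
  # hand-drawn 8x8 masks, ratio counted by enumeration
  m1 <- array(FALSE, c(8, 8)); m1[2:5, 2:5] <- TRUE
  m2 <- array(FALSE, c(8, 8)); m2[4:7, 3:6] <- TRUE
  inter <- sum(m1 & m2); un <- sum(m1 | m2)
  expect_equal(as.numeric(semanticIoU(m1, m2)), inter / un)
  # empty-vs-empty is defined as 1 and flagged
  e <- semanticIoU(array(FALSE, c(4, 4)), array(FALSE, c(4, 4)))
  expect_equal(as.numeric(e), 1)
  expect_true(attr(e, "flagged"))
  expect_error(semanticIoU(m1, matrix(TRUE, 4, 4)), "shape")
})

test_that("threshold optimisation returns the sweep argmax", {
  set.seed(11)
  gt <- array(FALSE, c(32, 32)); gt[8:20, 8:20] <- TRUE
  # probability equal to the mask: any threshold is perfect, lowest returned
  exact <- optimizeThreshold(gt * 1, gt)
  expect_equal(exact$best_iou, 1)
  expect_identical(exact$best_threshold, 1L)
  # inverted map: curve equals an exhaustive sweep
  inv <- optimizeThreshold(1 - gt, gt)
  p8 <- round((1 - gt) * 255)
  sweep <- vapply(1:254, function(t) {
    pred <- p8 >= t
    u <- sum(pred | gt)
    if (u == 0) 1 else sum(pred & gt) / u
  }, numeric(1))
  expect_equal(inv$curve$iou, sweep)
  expect_equal(inv$best_iou, max(sweep))
  # noisy graded map: returned threshold beats two arbitrary ones
  prob <- gt * 0.8 + matrix(rnorm(1024, 0, 0.05), 32, 32)
  res <- optimizeThreshold(prob, gt)
  p8n <- round((prob - min(prob)) / diff(range(prob)) * 255)
  iouAt <- function(t) as.numeric(semanticIoU(p8n >= t, gt))
  expect_gte(res$best_iou, iouAt(50))
  expect_gte(res$best_iou, iouAt(200))
  # argmax dominates every swept threshold
  expect_equal(res$best_iou, max(res$curve$iou))
  # constant map flagged at mid-scale
  flat <- optimizeThreshold(matrix(0.5, 8, 8), array(FALSE, c(8, 8)))
  expect_true(flat$flagged)
  expect_identical(flat$best_threshold, 127L)
})

test_that("instance matching is label-permutation invariant and exact", {
  sc <- makeNucleiScene(nObjects = 8, seed = 12)
  gt <- sc$labels
  # relabel arbitrarily
  perm <- sample(100 + seq_len(8))
  pred <- array(0L, dim(gt))
  for (k in 1:8) pred[gt == k] <- perm[k]
  m <- matchInstances(gt, pred, tau = 0.5)
  expect_identical(m$TP, 8L)
  expect_identical(m$FP, 0L)
  expect_identical(m$FN, 0L)
  expect_true(all(m$matches$iou == 1))
  # empty prediction
  m0 <- matchInstances(gt, array(0L, dim(gt)), tau = 0.5)
  expect_identical(c(m0$TP, m0$FP, m0$FN), c(0L, 0L, 5L + 3L))
  # empty gt with predictions
  m1 <- matchInstances(array(0L, dim(gt)), gt, tau = 0.5)
  expect_identical(c(m1$TP, m1$FP, m1$FN), c(0L, 8L, 0L))
})

test_that("optimal assignment agrees with exhaustive enumeration", {
  # merged/split scene at a low tau so ambiguous pairs enter the assignment
  sc <- makeMergedSplitScene()
  for (tau in c(0.2, 0.3, 0.5)) {
    m <- matchInstances(sc$gt, sc$pred, tau = tau)
    pairs <- countInstanceIoU(sc$gt, sc$pred)
    pairs <- pairs[pairs$iou >= tau, , drop = FALSE]
    want <- bruteAssign(pairs)
    expect_equal(sum(m$matches$iou), want$total, tolerance = 1e-12)
    expect_identical(m$TP, want$tp)
  }
  # random blob scenes with <= 8 instances
  for (seed in 13:17) {
    sc2 <- makeNucleiScene(nObjects = 6, seed = seed)
    noisyPred <- sc2$labels
    # erode-ish corruption: drop one object, shift another
    noisyPred[noisyPred == 1] <- 0
    sh <- array(0L, dim(noisyPred))
    sh[, 3:ncol(sh)] <- noisyPred[, 1:(ncol(sh) - 2)]
    m <- matchInstances(sc2$labels, sh, tau = 0.3)
    pairs <- countInstanceIoU(sc2$labels, sh)
    pairs <- pairs[pairs$iou >= 0.3, , drop = FALSE]
    want <- bruteAssign(pairs)
    expect_equal(sum(m$matches$iou), want$total, tolerance = 1e-12)
    expect_identical(m$TP, want$tp)
  }
})

test_that("greedy matching is available and one-to-one", {
  sc <- makeMergedSplitScene()
  g <- matchInstances(sc$gt, sc$pred, tau = 0.2, method = "greedy")
  expect_lte(g$TP, min(g$n_gt, g$n_pred))
  expect_false(any(duplicated(g$matches$gt)))
  expect_false(any(duplicated(g$matches$pred)))
})

test_that("instance scores follow the F1/SQ/RQ/PQ formulas", {
  # perfect match
  sc <- makeNucleiScene(nObjects = 5, seed = 18)
  m <- matchInstances(sc$labels, sc$labels)
  s <- instanceScores(m)
  for (f in c("precision", "recall", "f1", "mean_matched_iou", "RQ", "PQ")) {
    expect_equal(s[[f]], 1)
  }
  # hand arithmetic: TP=3, FP=1, FN=1, ious {0.9, 0.8, 0.7}
  fake <- structure(list(matches = data.frame(gt = 1:3, pred = 1:3,
                                              iou = c(0.9, 0.8, 0.7)),
                         TP = 3L, FP = 1L, FN = 1L, tau = 0.5,
                         method = "optimal", n_gt = 4L, n_pred = 4L),
                    class = "MatchResult")
  s2 <- instanceScores(fake)
  expect_equal(s2$f1, 0.75)
  expect_equal(s2$mean_matched_iou, 0.8)
  expect_equal(s2$RQ, 0.75)
  expect_equal(s2$PQ, 0.6)
  # no matches -> zeros, flagged
  none <- structure(list(matches = data.frame(gt = numeric(),
                                              pred = numeric(),
                                              iou = numeric()),
                         TP = 0L, FP = 2L, FN = 3L, tau = 0.5,
                         method = "optimal", n_gt = 3L, n_pred = 2L),
                    class = "MatchResult")
  s3 <- instanceScores(none)
  expect_true(s3$flagged)
  expect_equal(s3$PQ, 0)
})

test_that("scores are invariant under relabelling and joint D4 transforms,
           and a spurious prediction never helps", {
  sc <- makeNucleiScene(nObjects = 7, seed = 19)
  gt <- sc$labels
  pred <- gt
  pred[pred == 2] <- 0       # one miss
  base <- instanceScores(matchInstances(gt, pred))
  for (t in c("rot90", "flip_h", "transpose")) {
    s <- instanceScores(matchInstances(applyD4(gt, t), applyD4(pred, t)))
    expect_equal(s$PQ, base$PQ)
    expect_equal(s$f1, base$f1)
  }
  # add a spurious object: precision/f1/RQ/PQ must not increase
  sp <- pred
  sp[1:3, 1:3] <- 99L
  worse <- instanceScores(matchInstances(gt, sp))
  expect_lte(worse$precision, base$precision)
  expect_lte(worse$f1, base$f1)
  expect_lte(worse$RQ, base$RQ)
  expect_lte(worse$PQ, base$PQ)
})

test_that("instance IoU map paints matched IoU per predicted object", {
  sc <- makeNucleiScene(nObjects = 5, seed = 20)
  m <- matchInstances(sc$labels, sc$labels)
  map <- instanceIoUMap(sc$labels, m)
  expect_true(all(map[sc$labels > 0] == 1))
  expect_true(all(map[sc$labels == 0] == 0))
  # one unmatched predicted object paints 0
  pred <- sc$labels
  pred[1:4, 1:4] <- 99L
  m2 <- matchInstances(sc$labels, pred)
  map2 <- instanceIoUMap(pred, m2)
  expect_true(all(map2[pred == 99] == 0))
  lut <- setNames(m2$matches$iou, m2$matches$pred)
  for (p in m2$matches$pred) {
    expect_true(all(map2[pred == p] == lut[[as.character(p)]]))
  }
})

test_that("centroid export gives exact pixel centroids and dot stacks", {
  lab <- array(0L, c(8, 8))
  lab[3:5, 3:5] <- 1L   # rows/cols 2..4 in 0-based terms
  out <- exportCentroids(lab)
  expect_equal(out$table$x, 3)
  expect_equal(out$table$y, 3)
  expect_equal(getFrame(out$stack, 1)[4, 4], 1)
  # L-shaped instance: centroid equals the mean of enumerated pixels
  lab2 <- array(0L, c(8, 8))
  lab2[2:6, 2] <- 2L
  lab2[6, 2:5] <- 2L
  idx <- which(lab2 == 2L, arr.ind = TRUE)
  out2 <- exportCentroids(lab2, pixelSizeNm = 100)
  expect_equal(out2$table$y, mean(idx[, 1]) - 1)
  expect_equal(out2$table$x, mean(idx[, 2]) - 1)
  expect_equal(out2$table$x_nm, (mean(idx[, 2]) - 1 + 0.5) * 100)
  # two frames, two instances each
  fr <- array(0L, c(8, 8)); fr[1:2, 1:2] <- 1L; fr[6:7, 6:7] <- 2L
  out3 <- exportCentroids(list(fr, fr))
  expect_identical(nrow(out3$table), 4L)
  expect_equal(out3$table$frame, c(1, 1, 2, 2))
  expect_identical(nFrames(out3$stack), 2L)
})
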