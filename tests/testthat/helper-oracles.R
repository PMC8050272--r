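# Independent reference implementations used as oracles.  These are written
# naively (loops, enumeration, rasterisation) and share no code with the
# package internals they check.

# SSIM by direct window loops over a replicate-padded image
naiveSSIM <- function(ref, img, K1 = 0.01, K2 = 0.03, L = 1, sigma = 1.5,
                      size = 11L) {
  r <- (size - 1L) / 2L
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  pad <- function(m) {
    m <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), ]
    m[, c(rep(1, r), seq_len(ncol(m)), rep(ncol(m), r))]
  }
  pr <- pad(ref); pi_ <- pad(img)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  out <- array(NA_real_, dim(ref))
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      wx <- pr[i:(i + 2 * r), j:(j + 2 * r)]
      wy <- pi_[i:(i + 2 * r), j:(j + 2 * r)]
      m1 <- sum(w * wx); m2 <- sum(w * wy)
      v1 <- sum(w * wx^2) - m1^2
      v2 <- sum(w * wy^2) - m2^2
      cv <- sum(w * wx * wy) - m1 * m2
      out[i, j] <- ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                   ((m1^2 + m2^2 + C1) * (v1 + v2 + C2))
    }
  }
  out
}

# exhaustive one-to-one assignment maximising total IoU among candidate
# pairs (data frame gt/pred/iou); returns the best TP count and total IoU
bruteAssign <- function(pairs) {
  best <- list(total = 0, tp = 0L)
  recur <- function(i, usedG, usedP, total, tp) {
    if (total + (nrow(pairs) - i + 1) < best$total - 1e-12) {
      # continue anyway: the bound is loose, recursion is cheap at this size
    }
    if (i > nrow(pairs)) {
      if (total > best$total + 1e-12 ||
          (abs(total - best$total) <= 1e-12 && tp > best$tp)) {
        best <<- list(total = total, tp = tp)
      }
      return(invisible())
    }
    recur(i + 1L, usedG, usedP, total, tp)   # skip pair i
    g <- pairs$gt[i]; p <- pairs$pred[i]
    if (!(g %in% usedG) && !(p %in% usedP)) {
      recur(i + 1L, c(usedG, g), c(usedP, p), total + pairs$iou[i], tp + 1L)
    }
  }
  recur(1L, numeric(), numeric(), 0, 0L)
  best
}

# pairwise instance IoU by direct pixel counting
countInstanceIoU <- function(gt, pred) {
  out <- NULL
  for (g in setdiff(unique(as.vector(gt)), 0)) {
    for (p in setdiff(unique(as.vector(pred)), 0)) {
      inter <- sum(gt == g & pred == p)
      if (inter > 0) {
        un <- sum(gt == g | pred == p)
        out <- rbind(out, data.frame(gt = g, pred = p, iou = inter / un))
      }
    }
  }
  if (is.null(out)) data.frame(gt = numeric(), pred = numeric(),
                               iou = numeric()) else out
}

# AP by explicit envelope construction and rectangle summation
naiveAP <- function(tp, nGt) {
  if (nGt == 0) return(0)
  n <- length(tp)
  if (n == 0) return(0)
  rec <- cumsum(tp) / nGt
  prec <- cumsum(tp) / seq_len(n)
  env <- numeric(n)
  for (i in seq_len(n)) env[i] <- max(prec[i:n])
  ap <- 0
  prev <- 0
  for (i in seq_len(n)) {
    ap <- ap + (rec[i] - prev) * env[i]
    prev <- rec[i]
  }
  ap
}

# independent greedy confidence-ranked detection matcher (one class)
naiveMatch <- function(gtBoxes, predBoxes, tau) {
  iou <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ord <- order(-predBoxes$confidence, predBoxes$image, predBoxes$xmin,
               predBoxes$ymin, predBoxes$xmax, predBoxes$ymax)
  predBoxes <- predBoxes[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gtBoxes))
  tp <- logical(nrow(predBoxes))
  for (i in seq_len(nrow(predBoxes))) {
    bestIoU <- 0; bestJ <- NA
    for (j in seq_len(nrow(gtBoxes))) {
      if (used[j] || gtBoxes$image[j] != predBoxes$image[i]) next
      v <- iou(unlist(predBoxes[i, c("xmin", "ymin", "xmax", "ymax")]),
               unlist(gtBoxes[j, c("xmin", "ymin", "xmax", "ymax")]))
      if (v > bestIoU) { bestIoU <- v; bestJ <- j }
    }
    if (!is.na(bestJ) && bestIoU >= tau) {
      tp[i] <- TRUE
      used[bestJ] <- TRUE
    }
  }
  tp
}

# rasterise a half-open box into a logical image
rasterBox <- function(box, shape) {
  m <- array(FALSE, shape)
  rows <- (box["ymin"] + 1):box["ymax"]
  cols <- (box["xmin"] + 1):box["xmax"]
  m[rows, cols] <- TRUE
  m
}

# cluster points by single-linkage within `radius` (union-find)
unionFindClusters <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= radius) {
        parent[find(i)] <- find(j)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# simple 8x8 instance scene with one merged and one split prediction
makeMergedSplitScene <- function() {
  gt <- array(0L, c(12L, 12L))
  gt[2:3, 2:3] <- 1L; gt[2:3, 5:6] <- 2L; gt[6:7, 2:3] <- 3L
  gt[6:7, 6:7] <- 4L; gt[10:11, 2:3] <- 5L; gt[10:11, 8:9] <- 6L
  pred <- array(0L, c(12L, 12L))
  pred[2:3, 2:6] <- 10L               # merges gt 1 and 2
  pred[6:7, 2:3] <- 11L               # matches gt 3
  pred[6, 6:7] <- 12L; pred[7, 6:7] <- 13L  # splits gt 4
  pred[10:11, 2:3] <- 14L             # matches gt 5
  pred[10:11, 8:9] <- 15L             # matches gt 6
  list(gt = gt, pred = pred)
}
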