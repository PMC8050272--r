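# Semantic and instance segmentation quality control: IoU, automatic
# threshold optimisation on probability maps, one-to-one instance matching
# (optimal assignment), F1 / Panoptic Quality, per-object IoU maps and
# centroid export for tracking.

#' Intersection-over-union of two binary masks
#'
#' `|a & b| / |a | b|`.  Two empty masks have no overlap to measure; the
#' value is defined as 1 and flagged, so batch QC over empty tiles does not
#' propagate NaN.
#'
#' @param a,b logical (or 0/1 numeric) matrices of identical shape.
#' @return IoU in `[0, 1]` with attribute `flagged` when both masks are empty.
#' @export
semanticIoU <- function(a, b) {
  stopIfShapeMismatch(a, b, "masks")
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0L) {
    out <- 1
    attr(out, "flagged") <- TRUE
    return(out)
  }
  out <- sum(a & b) / un
  attr(out, "flagged") <- FALSE
  out
}

#' Optimal binarisation threshold for a probability map
#'
#' Rescales the map to 8-bit (min-max for float inputs; integer maps in
#' 0..255 are used as-is), sweeps integer thresholds 1..254, binarises at
#' `value >= threshold` and scores each against the ground-truth mask with
#' [semanticIoU()].  Returns the threshold with the highest IoU; ties break
#' toward the lowest threshold.  A constant map cannot be thresholded: the
#' mid-scale threshold 127 is returned flagged.
#'
#' @param probability 2D numeric matrix (any range) or 8-bit integer matrix.
#' @param gt ground-truth binary mask of the same shape.
#' @return list with `best_threshold`, `best_iou`, `curve` (data frame of
#'   threshold/iou), and `flagged`.
#' @export
optimizeThreshold <- function(probability, gt) {
  stopIfShapeMismatch(probability, gt)
  rng <- range(probability)
  if (rng[1L] == rng[2L]) {
    return(list(best_threshold = 127L, best_iou = NA_real_,
                curve = data.frame(threshold = integer(), iou = numeric()),
                flagged = TRUE))
  }
  isInt8 <- all(probability == round(probability)) && rng[1L] >= 0 &&
    rng[2L] <= 255
  p8 <- if (isInt8) probability
        else round((probability - rng[1L]) / (rng[2L] - rng[1L]) * 255)
  thresholds <- 1:254
  iou <- vapply(thresholds,
                function(t) as.numeric(semanticIoU(p8 >= t, gt)),
                numeric(1L))
  best <- which.max(iou)   # which.max takes the first (lowest) on ties
  list(best_threshold = thresholds[best], best_iou = iou[best],
       curve = data.frame(threshold = thresholds, iou = iou),
       flagged = FALSE)
}

# pairwise IoU table between instances of two label images; rows gt, cols
# pred, only pairs with non-zero overlap are returned
pairwiseInstanceIoU <- function(gt, pred) {
  gtLabels <- sort(setdiff(unique(as.vector(gt)), 0))
  predLabels <- sort(setdiff(unique(as.vector(pred)), 0))
  if (!length(gtLabels) || !length(predLabels)) {
    return(list(pairs = data.frame(gt = numeric(), pred = numeric(),
                                   iou = numeric()),
                gtLabels = gtLabels, predLabels = predLabels))
  }
  both <- gt > 0 & pred > 0
  areaG <- table(factor(gt[gt > 0], levels = gtLabels))
  areaP <- table(factor(pred[pred > 0], levels = predLabels))
  if (!any(both)) {
    pairs <- data.frame(gt = numeric(), pred = numeric(), iou = numeric())
  } else {
    ov <- table(factor(gt[both], levels = gtLabels),
                factor(pred[both], levels = predLabels))
    idx <- which(ov > 0, arr.ind = TRUE)
    inter <- ov[idx]
    g <- gtLabels[idx[, 1L]]
    p <- predLabels[idx[, 2L]]
    uni <- as.numeric(areaG[idx[, 1L]]) + as.numeric(areaP[idx[, 2L]]) - inter
    pairs <- data.frame(gt = g, pred = p, iou = as.numeric(inter) / uni)
  }
  list(pairs = pairs, gtLabels = gtLabels, predLabels = predLabels)
}

#' One-to-one instance matching between label images
#'
#' Computes IoU between every overlapping (ground-truth, predicted) instance
#' pair, keeps pairs with `iou >= tau`, and assigns them one-to-one.  The
#' default assignment is optimal (maximises total IoU via maximum-weight
#' bipartite matching); `method = "greedy"` takes pairs in decreasing IoU
#' order instead.  Matched pairs are TP; unmatched predictions FP; unmatched
#' ground-truth instances FN.
#'
#' @param gt,pred integer label matrices (0 = background) of identical shape.
#' @param tau IoU acceptance threshold in (0, 1); default 0.5.
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return list of class `"MatchResult"`: `matches` (data frame gt/pred/iou),
#'   `TP`, `FP`, `FN`, `tau`, `method`, `n_gt`, `n_pred`.
#' @export
matchInstances <- function(gt, pred, tau = 0.5, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(tau > 0, tau < 1)
  stopIfShapeMismatch(gt, pred, "label images")
  pw <- pairwiseInstanceIoU(gt, pred)
  cand <- pw$pairs[pw$pairs$iou >= tau, , drop = FALSE]
  matches <- cand[0L, , drop = FALSE]
  if (nrow(cand)) {
    if (method == "greedy") {
      ord <- order(-cand$iou, cand$gt, cand$pred)
      usedG <- usedP <- character()
      keep <- logical(nrow(cand))
      for (i in ord) {
        gk <- as.character(cand$gt[i]); pk <- as.character(cand$pred[i])
        if (!(gk %in% usedG) && !(pk %in% usedP)) {
          keep[i] <- TRUE
          usedG <- c(usedG, gk); usedP <- c(usedP, pk)
        }
      }
      matches <- cand[keep, , drop = FALSE]
    } else {
      gIdx <- match(cand$gt, pw$gtLabels)
      pIdx <- match(cand$pred, pw$predLabels)
      nG <- length(pw$gtLabels)
      edges <- rbind(gIdx, nG + pIdx)
      g <- igraph::make_bipartite_graph(
        c(rep(TRUE, nG), rep(FALSE, length(pw$predLabels))),
        as.vector(edges), directed = FALSE)
      m <- igraph::max_bipartite_match(g, weights = cand$iou)
      sel <- which(!is.na(m$matching[seq_len(nG)]))
      if (length(sel)) {
        pick <- data.frame(gt = pw$gtLabels[sel],
                           pred = pw$predLabels[m$matching[sel] - nG])
        key <- paste(pick$gt, pick$pred)
        matches <- cand[paste(cand$gt, cand$pred) %in% key, , drop = FALSE]
      }
    }
  }
  rownames(matches) <- NULL
  out <- list(matches = matches, TP = nrow(matches),
              FP = length(pw$predLabels) - nrow(matches),
              FN = length(pw$gtLabels) - nrow(matches),
              tau = tau, method = method,
              n_gt = length(pw$gtLabels), n_pred = length(pw$predLabels))
  class(out) <- "MatchResult"
  out
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult (tau = %g, %s): TP %d, FP %d, FN %d\n",
              x$tau, x$method, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Instance-level scores from a match result
#'
#' Precision, recall, F1 = `2TP/(2TP+FP+FN)`, segmentation quality
#' SQ = mean IoU over matched pairs, recognition quality
#' RQ = `TP/(TP + FP/2 + FN/2)` (equal to F1) and Panoptic Quality
#' PQ = SQ * RQ.  With no matches SQ is 0 and the result is flagged.
#'
#' @param match a `MatchResult` from [matchInstances()].
#' @return list of class `"InstanceScores"` with `precision`, `recall`,
#'   `f1`, `mean_matched_iou` (SQ), `RQ`, `PQ`, `flagged`.
#' @export
instanceScores <- function(match) {
  stopifnot(inherits(match, "MatchResult"))
  TP <- match$TP; FP <- match$FP; FN <- match$FN
  div <- function(num, den) if (den == 0) 0 else num / den
  sq <- if (TP > 0) mean(match$matches$iou) else 0
  rq <- div(TP, TP + FP / 2 + FN / 2)
  out <- list(precision = div(TP, TP + FP), recall = div(TP, TP + FN),
              f1 = div(2 * TP, 2 * TP + FP + FN),
              mean_matched_iou = sq, RQ = rq, PQ = sq * rq,
              flagged = TP == 0)
  class(out) <- "InstanceScores"
  out
}

#' @export
print.InstanceScores <- function(x, ...) {
  cat(sprintf(
    "InstanceScores: precision %.3f recall %.3f F1 %.3f SQ %.3f RQ %.3f PQ %.3f\n",
    x$precision, x$recall, x$f1, x$mean_matched_iou, x$RQ, x$PQ))
  invisible(x)
}

#' Per-object IoU map
#'
#' Paints every predicted instance with the IoU of its matched ground-truth
#' instance (0 when unmatched); background stays 0.  Localises where a
#' segmentation model fails within the field of view.
#'
#' @param pred predicted label matrix.
#' @param match a `MatchResult` from [matchInstances()] for the same images.
#' @return numeric matrix of per-pixel matched IoU.
#' @export
instanceIoUMap <- function(pred, match) {
  stopifnot(inherits(match, "MatchResult"))
  out <- array(0, dim(pred))
  if (nrow(match$matches)) {
    lut <- stats::setNames(match$matches$iou, match$matches$pred)
    fg <- pred > 0
    vals <- lut[as.character(pred[fg])]
    vals[is.na(vals)] <- 0
    out[fg] <- vals
  }
  out
}

#' Export instance centroids for tracking
#'
#' For every frame and instance, computes the pixel centroid (mean of
#' member pixel coordinates, 0-based, pixel-centre convention) and returns a
#' tracking table plus a companion stack with a single white pixel at each
#' rounded centroid — directly usable as a spot image for tracking tools.
#'
#' @param labels list of integer label matrices (one per frame) or a single
#'   matrix.
#' @param pixelSizeNm optional pixel pitch; when given, `x_nm`/`y_nm`
#'   columns are added using `(pixel + 0.5) * pixelSizeNm`.
#' @return list with `table` (data frame: frame, label, x, y in 0-based
#'   pixels and optionally nm) and `stack` (an [ImageStack-class] of dots).
#' @export
exportCentroids <- function(labels, pixelSizeNm = NA_real_) {
  if (is.matrix(labels)) labels <- list(labels)
  rows <- list()
  dots <- vector("list", length(labels))
  for (f in seq_along(labels)) {
    lab <- labels[[f]]
    dot <- array(0, dim(lab))
    ids <- sort(setdiff(unique(as.vector(lab)), 0))
    for (id in ids) {
      idx <- which(lab == id, arr.ind = TRUE)
      cy <- mean(idx[, 1L]) - 1   # 0-based row
      cx <- mean(idx[, 2L]) - 1   # 0-based col
      rows[[length(rows) + 1L]] <- data.frame(frame = f, label = id,
                                              x = cx, y = cy)
      dot[round(cy) + 1L, round(cx) + 1L] <- 1
    }
    dots[[f]] <- dot
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(frame = numeric(), label = numeric(),
                         x = numeric(), y = numeric())
  if (!is.na(pixelSizeNm)) {
    tab$x_nm <- (tab$x + 0.5) * pixelSizeNm
    tab$y_nm <- (tab$y + 0.5) * pixelSizeNm
  }
  list(table = tab,
       stack = ImageStack(dots, pixelSizeNm = pixelSizeNm, dtype = "uint8"))
}
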