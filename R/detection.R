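# Object-detection quality control: box IoU, confidence-ranked matching,
# per-class precision-recall curves, AP / mAP and F1 at an operating
# confidence.

#' Intersection-over-union of two axis-aligned boxes
#'
#' Boxes are `c(xmin, ymin, xmax, ymax)` in 0-based half-open pixel
#' coordinates.  Disjoint boxes score 0.
#'
#' @param a,b numeric vectors `c(xmin, ymin, xmax, ymax)` (or 1-row data
#'   frames with those columns).
#' @return IoU in `[0, 1]`.
#' @export
boxIoU <- function(a, b) {
  toVec <- function(z) {
    if (is.data.frame(z)) unlist(z[1L, c("xmin", "ymin", "xmax", "ymax")])
    else as.numeric(z[1:4])
  }
  a <- toVec(a); b <- toVec(b)
  if (a[3L] <= a[1L] || a[4L] <= a[2L] || b[3L] <= b[1L] || b[4L] <= b[2L]) {
    stop("degenerate box: xmax must exceed xmin and ymax must exceed ymin")
  }
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
           (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  inter / union
}

# flatten a list of DetectionSets into one data frame with an image column
flattenDetections <- function(sets) {
  if (methods::is(sets, "DetectionSet")) sets <- list(sets)
  dfs <- lapply(sets, function(s) {
    b <- s@boxes
    if (!nrow(b)) return(NULL)
    b$image <- s@imageName
    b
  })
  dfs <- Filter(Negate(is.null), dfs)
  if (!length(dfs)) {
    return(data.frame(class = character(), xmin = numeric(), ymin = numeric(),
                      xmax = numeric(), ymax = numeric(),
                      confidence = numeric(), image = character()))
  }
  do.call(rbind, dfs)
}

#' Match predicted boxes to ground truth, per class, ranked by confidence
#'
#' Within each class, predictions are sorted by decreasing confidence (ties
#' broken by image name, then box coordinates, for reproducibility).  Each
#' prediction is a true positive if its IoU with a not-yet-matched
#' ground-truth box of the same class in the same image reaches `tau` (the
#' highest-IoU available box is consumed); otherwise it is a false
#' positive.  Ground-truth boxes left unmatched are false negatives — in
#' particular, a second detection of an already-matched object counts as FP.
#'
#' @param gt,pred lists of [DetectionSet-class] (ground truth carries `NA`
#'   confidences; every prediction must carry one).
#' @param tau IoU threshold (default 0.5, the mAP@0.5 convention).
#' @return list of class `"DetectionMatches"`: `records` (data frame class /
#'   image / confidence / tp / iou, ranked within class), `n_gt` (named
#'   per-class ground-truth counts), `tau`.
#' @export
matchDetections <- function(gt, pred, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  g <- flattenDetections(gt)
  p <- flattenDetections(pred)
  if (nrow(p) && any(is.na(p$confidence))) {
    stop("every prediction must carry a confidence score")
  }
  classes <- sort(unique(c(g$class, p$class)))
  nGt <- vapply(classes, function(cl) sum(g$class == cl), numeric(1L))
  records <- list()
  for (cl in classes) {
    pc <- p[p$class == cl, , drop = FALSE]
    gc <- g[g$class == cl, , drop = FALSE]
    used <- rep(FALSE, nrow(gc))
    if (nrow(pc)) {
      ord <- order(-pc$confidence, pc$image, pc$xmin, pc$ymin, pc$xmax,
                   pc$ymax)
      pc <- pc[ord, , drop = FALSE]
      tp <- logical(nrow(pc))
      iou <- numeric(nrow(pc))
      for (i in seq_len(nrow(pc))) {
        cand <- which(!used & gc$image == pc$image[i])
        if (length(cand)) {
          ious <- vapply(cand, function(j) boxIoU(pc[i, ], gc[j, ]),
                         numeric(1L))
          best <- which.max(ious)
          if (ious[best] >= tau) {
            tp[i] <- TRUE
            iou[i] <- ious[best]
            used[cand[best]] <- TRUE
          }
        }
      }
      records[[cl]] <- data.frame(class = cl, image = pc$image,
                                  confidence = pc$confidence, tp = tp,
                                  iou = iou)
    }
  }
  recs <- if (length(records)) do.call(rbind, records)
          else data.frame(class = character(), image = character(),
                          confidence = numeric(), tp = logical(),
                          iou = numeric())
  rownames(recs) <- NULL
  out <- list(records = recs, n_gt = nGt, tau = tau)
  class(out) <- "DetectionMatches"
  out
}

#' Precision-recall curve and average precision for one class
#'
#' Builds the cumulative precision/recall sequence along the confidence
#' ranking and integrates the precision envelope over recall.  The default
#' all-point interpolation makes precision monotonically non-increasing from
#' the right before integration; `interpolation = "11point"` averages the
#' interpolated precision at recalls 0, 0.1, ..., 1 (the classic PASCAL VOC
#' protocol).
#'
#' @param ranked data frame with a logical `tp` column, already ranked by
#'   decreasing confidence (one class), e.g. a class subset of
#'   [matchDetections()] records.
#' @param nGt number of ground-truth boxes for this class.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return list of class `"PRCurve"`: `recall`, `precision`, `ap`,
#'   `interpolation`, `flagged` (`TRUE` when `nGt` is 0).
#' @export
prCurve <- function(ranked, nGt, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(nGt >= 0)
  n <- nrow(ranked)
  if (nGt == 0L) {
    return(structure(list(recall = numeric(n), precision = numeric(n),
                          ap = 0, interpolation = interpolation,
                          flagged = TRUE), class = "PRCurve"))
  }
  if (n == 0L) {
    return(structure(list(recall = numeric(0), precision = numeric(0),
                          ap = 0, interpolation = interpolation,
                          flagged = FALSE), class = "PRCurve"))
  }
  ctp <- cumsum(ranked$tp)
  cfp <- cumsum(!ranked$tp)
  recall <- ctp / nGt
  precision <- ctp / (ctp + cfp)
  env <- rev(cummax(rev(precision)))
  ap <- if (interpolation == "all") {
    sum(diff(c(0, recall)) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- recall >= r
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1L)))
  }
  structure(list(recall = recall, precision = precision, ap = ap,
                 interpolation = interpolation, flagged = FALSE),
            class = "PRCurve")
}

#' @export
print.PRCurve <- function(x, ...) {
  cat(sprintf("PRCurve (%s interpolation): %d point(s), AP %.4f%s\n",
              x$interpolation, length(x$recall), x$ap,
              if (x$flagged) " [flagged: no ground truth]" else ""))
  invisible(x)
}

#' Per-class PR curves and mean average precision
#'
#' @param matches a `DetectionMatches` object from [matchDetections()].
#' @param interpolation AP interpolation rule, see [prCurve()].
#' @return list of class `"MAPResult"`: `curves` (named per-class
#'   [prCurve()] results), `ap` (named vector over classes present in the
#'   ground truth), `map` (their unweighted mean).
#' @export
mapScore <- function(matches, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(matches, "DetectionMatches"))
  classes <- names(matches$n_gt)
  curves <- lapply(classes, function(cl) {
    prCurve(matches$records[matches$records$class == cl, , drop = FALSE],
            matches$n_gt[[cl]], interpolation)
  })
  names(curves) <- classes
  present <- classes[matches$n_gt > 0]
  if (!length(present)) stop("no class has ground-truth boxes")
  ap <- vapply(curves[present], `[[`, numeric(1L), "ap")
  structure(list(curves = curves, ap = ap, map = mean(ap),
                 interpolation = interpolation), class = "MAPResult")
}

#' @export
print.MAPResult <- function(x, ...) {
  cat(sprintf("mAP (%s interpolation): %.4f\n", x$interpolation, x$map))
  for (cl in names(x$ap)) cat(sprintf("  AP[%s] = %.4f\n", cl, x$ap[[cl]]))
  invisible(x)
}

#' Detection F1 at an operating confidence
#'
#' Counts TP/FP among predictions with `confidence >= confidence` and FN as
#' ground-truth boxes not matched by any such prediction;
#' `F1 = 2TP / (2TP + FP + FN)`.  The operating confidence is a recorded
#' parameter of the score.
#'
#' @param matches a `DetectionMatches` object.
#' @param confidence operating confidence threshold (default 0.3).
#' @return F1 scalar with attributes `TP`, `FP`, `FN`, `confidence`.
#' @export
detectionF1 <- function(matches, confidence = 0.3) {
  stopifnot(inherits(matches, "DetectionMatches"))
  r <- matches$records[matches$records$confidence >= confidence, ,
                       drop = FALSE]
  TP <- sum(r$tp)
  FP <- sum(!r$tp)
  FN <- sum(matches$n_gt) - TP
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  attr(f1, "TP") <- TP
  attr(f1, "FP") <- FP
  attr(f1, "FN") <- FN
  attr(f1, "confidence") <- confidence
  f1
}
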