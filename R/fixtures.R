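# Deterministic synthetic-data generators.  Every generator is a pure
# function of its arguments (seed included), so QC modules can be exercised
# in closed loop: perfect predictions must score perfectly and known
# corruption must move every score in the analytically expected direction.

# paint one rotated ellipse; returns linear pixel indices
ellipsePixels <- function(shape, cy, cx, a, b, theta) {
  h <- shape[1L]; w <- shape[2L]
  r0 <- max(1L, floor(cy - a - b)); r1 <- min(h, ceiling(cy + a + b))
  c0 <- max(1L, floor(cx - a - b)); c1 <- min(w, ceiling(cx + a + b))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  (cols[idx[, 2L]] - 1L) * h + rows[idx[, 1L]]
}

#' Synthetic nuclei scene with exact instance ground truth
#'
#' Packs `nObjects` non-overlapping random ellipses ("nuclei") into the
#' image by rejection sampling, assigns each a random intensity, and
#' returns the exact label image together with a smoothed fluorescence
#' render — a stand-in for a stained-nuclei field with hand-annotated
#' masks.
#'
#' @param shape `c(height, width)` in pixels.
#' @param nObjects number of nuclei (>= 0).
#' @param sizeRange semi-axis range in pixels.
#' @param seed RNG seed.
#' @param maxAttempts placement attempts per object before giving up.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `fluorescence` (numeric matrix in roughly `[0.1, 1.1]`).
#' @export
makeNucleiScene <- function(shape = c(128L, 128L), nObjects = 20L,
                            sizeRange = c(5, 10), seed = 1,
                            maxAttempts = 200L) {
  stopifnot(nObjects >= 0L, all(sizeRange > 0))
  withSeed(seed, {
    labels <- array(0L, shape)
    intens <- array(0, shape)
    for (k in seq_len(nObjects)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        a <- stats::runif(1L, sizeRange[1L], sizeRange[2L])
        b <- stats::runif(1L, sizeRange[1L], sizeRange[2L])
        th <- stats::runif(1L, 0, pi)
        cy <- stats::runif(1L, a + b + 1, shape[1L] - a - b - 1)
        cx <- stats::runif(1L, a + b + 1, shape[2L] - a - b - 1)
        px <- ellipsePixels(shape, cy, cx, a, b, th)
        if (length(px) && all(labels[px] == 0L)) {
          labels[px] <- k
          intens[px] <- stats::runif(1L, 0.5, 1)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place object %d after %d attempts", k,
                     maxAttempts))
      }
    }
    fluor <- gaussSmooth(intens, 1, 7L) + 0.1
    list(labels = labels, fluorescence = fluor)
  })
}

#' Degrade a clean image with Poisson shot noise and Gaussian read noise
#'
#' `Poisson(clean * poissonScale) / poissonScale + Normal(0, gaussianSigma)`;
#' large `poissonScale` approaches the clean image, small values give heavy
#' shot noise.
#'
#' @param clean non-negative matrix.
#' @param gaussianSigma additive Gaussian noise sd.
#' @param poissonScale photon scaling of the shot-noise term.
#' @param seed RNG seed.
#' @return noisy matrix of the same shape.
#' @export
makeNoisyPair <- function(clean, gaussianSigma = 0.1, poissonScale = 100,
                          seed = 1) {
  if (min(clean) < 0) stop("clean image must be non-negative")
  stopifnot(poissonScale > 0, gaussianSigma >= 0)
  withSeed(seed, {
    noisy <- stats::rpois(length(clean), clean * poissonScale) / poissonScale +
      stats::rnorm(length(clean), 0, gaussianSigma)
    array(noisy, dim(clean))
  })
}

#' Synthetic object-detection scene with countable corruption
#'
#' Draws textured elliptical blobs with class-dependent aspect ratios,
#' derives their exact bounding boxes as ground truth, and builds a
#' prediction set from the ground truth by dropping `round(dropFraction *
#' n)` boxes, jittering a fraction by a few pixels, and adding
#' `round(falseFraction * n)` false boxes in free areas.  Kept boxes draw
#' confidences above every false box, so with no corruption the scene
#' scores mAP = 1 and with drops only the full-ranking recall is exactly
#' `1 - round(dropFraction * n) / n`.
#'
#' @param shape `c(height, width)` pixels.
#' @param nObjects number of ground-truth objects.
#' @param classes class names cycled over the objects.
#' @param dropFraction fraction of GT boxes absent from the prediction.
#' @param jitterFraction fraction of kept boxes shifted by `jitterPx`.
#' @param falseFraction false-positive boxes as a fraction of `nObjects`.
#' @param jitterPx jitter amplitude (pixels).
#' @param seed RNG seed.
#' @return list with `image` (matrix), `gt` and `pred`
#'   ([DetectionSet-class]), and the realised counts `n_dropped`,
#'   `n_false`.
#' @export
makeDetectionScene <- function(shape = c(128L, 128L), nObjects = 12L,
                               classes = c("elongated", "rounded",
                                           "dividing", "spread"),
                               dropFraction = 0, jitterFraction = 0,
                               falseFraction = 0, jitterPx = 2L, seed = 1) {
  stopifnot(dropFraction >= 0, dropFraction <= 1, falseFraction >= 0,
            jitterFraction >= 0, jitterFraction <= 1)
  aspect <- c(elongated = 3, rounded = 1, dividing = 1.4, spread = 2)
  withSeed(seed, {
    img <- array(stats::rnorm(prod(shape), 0.1, 0.02), shape)
    boxes <- NULL
    cls <- rep_len(classes, nObjects)
    for (k in seq_len(nObjects)) {
      asp <- aspect[[match(cls[k], names(aspect), nomatch = 1L)]]
      for (att in 1:500) {
        b <- stats::runif(1L, 3, 5)
        a <- b * asp
        th <- sample(c(0, pi / 2), 1L)
        halfW <- abs(a * cos(th)) + abs(b * sin(th))
        halfH <- abs(a * sin(th)) + abs(b * cos(th))
        cy <- stats::runif(1L, halfH + 2, shape[1L] - halfH - 2)
        cx <- stats::runif(1L, halfW + 2, shape[2L] - halfW - 2)
        new <- data.frame(class = cls[k],
                          xmin = floor(cx - halfW), ymin = floor(cy - halfH),
                          xmax = ceiling(cx + halfW),
                          ymax = ceiling(cy + halfH),
                          confidence = NA_real_)
        clear <- is.null(boxes) || all(vapply(seq_len(nrow(boxes)),
          function(i) boxIoU(new, boxes[i, ]) == 0, logical(1L)))
        if (clear) {
          px <- ellipsePixels(shape, cy, cx, a, b, th)
          img[px] <- img[px] + stats::runif(1L, 0.5, 1)
          boxes <- rbind(boxes, new)
          break
        }
        if (att == 500L) stop("could not place detection scene objects")
      }
    }
    gt <- DetectionSet("scene", boxes)
    # prediction = GT minus drops, plus jitter, plus false boxes
    nDrop <- round(dropFraction * nObjects)
    keep <- if (nDrop > 0) {
      sort(sample(nObjects, nObjects - nDrop))
    } else seq_len(nObjects)
    pb <- boxes[keep, , drop = FALSE]
    if (nrow(pb)) {
      pb$confidence <- stats::runif(nrow(pb), 0.6, 1)
      nJit <- round(jitterFraction * nrow(pb))
      if (nJit > 0) {
        ji <- sample(nrow(pb), nJit)
        pb$xmin[ji] <- pb$xmin[ji] + jitterPx
        pb$xmax[ji] <- pb$xmax[ji] + jitterPx
      }
    }
    nFalse <- round(falseFraction * nObjects)
    for (k in seq_len(nFalse)) {
      for (att in 1:500) {
        sz <- stats::runif(2L, 6, 14)
        x0 <- stats::runif(1L, 0, shape[2L] - sz[1L])
        y0 <- stats::runif(1L, 0, shape[1L] - sz[2L])
        new <- data.frame(class = sample(classes, 1L),
                          xmin = floor(x0), ymin = floor(y0),
                          xmax = floor(x0) + ceiling(sz[1L]),
                          ymax = floor(y0) + ceiling(sz[2L]),
                          confidence = stats::runif(1L, 0.1, 0.5))
        overlaps <- any(vapply(seq_len(nrow(boxes)),
          function(i) boxIoU(new, boxes[i, ]) > 0, logical(1L)))
        if (!overlaps) {
          pb <- rbind(pb, new)
          break
        }
        if (att == 500L) stop("could not place false boxes")
      }
    }
    list(image = img, gt = gt, pred = DetectionSet("scene", pb),
         n_dropped = nDrop, n_false = nFalse)
  })
}

#' Synthetic drifting SMLM localisation table
#'
#' A structured scene of fixed emitters, each localised on every frame with
#' isotropic Gaussian localisation error, rigidly translated by a linear
#' drift reaching `driftNm` at the last frame.  Returns the table and the
#' exact per-frame drift applied, for parameter-recovery tests of
#' [estimateDrift()].
#'
#' @param nEmitters number of fixed emitters.
#' @param nFrames number of frames.
#' @param fovNm field-of-view side (nm).
#' @param driftNm `c(dx, dy)` total drift at the last frame (nm).
#' @param jitterNm per-localisation error sd (nm).
#' @param seed RNG seed.
#' @return list with `table` (a [LocalisationTable-class]) and `trueDrift`
#'   (data frame frame/dx/dy).
#' @export
makeDriftedLocalisations <- function(nEmitters = 60L, nFrames = 100L,
                                     fovNm = 10000, driftNm = c(100, -60),
                                     jitterNm = 8, seed = 1) {
  withSeed(seed, {
    ex <- stats::runif(nEmitters, 0.1 * fovNm, 0.9 * fovNm)
    ey <- stats::runif(nEmitters, 0.1 * fovNm, 0.9 * fovNm)
    frac <- (seq_len(nFrames) - 1) / (nFrames - 1)
    rows <- lapply(seq_len(nFrames), function(f) {
      data.frame(frame = f,
                 x = ex + frac[f] * driftNm[1L] +
                   stats::rnorm(nEmitters, 0, jitterNm),
                 y = ey + frac[f] * driftNm[2L] +
                   stats::rnorm(nEmitters, 0, jitterNm),
                 photons = stats::rpois(nEmitters, 1000),
                 sigma = 150)
    })
    list(table = LocalisationTable(do.call(rbind, rows)),
         trueDrift = data.frame(frame = seq_len(nFrames),
                                dx = frac * driftNm[1L],
                                dy = frac * driftNm[2L]))
  })
}
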