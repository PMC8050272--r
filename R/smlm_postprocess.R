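# Localisation post-processing: histogram rendering, spot extraction from
# reconstructed images, merging of emission events split across consecutive
# frames, and drift estimation/correction by cross-correlation of
# time-binned reconstructions.

#' Render a localisation table as a 2D count histogram
#'
#' Bins localisations on a grid of pitch `renderPixelNm`; total counts are
#' preserved before the optional Gaussian blur.
#'
#' @param table a [LocalisationTable-class].
#' @param renderPixelNm rendering pixel pitch (nm).
#' @param blurSigmaPx optional Gaussian blur sd in rendered pixels (0 = off).
#' @param extentNm rendered extent (nm); defaults to the maximum coordinate.
#'   Pass a common extent to make several renderings comparable.
#' @return numeric matrix (rows = y, cols = x) with attributes
#'   `renderPixelNm` and `flagged` (TRUE for an empty table).
#' @export
renderHistogram <- function(table, renderPixelNm, blurSigmaPx = 0,
                            extentNm = NULL) {
  stopifnot(methods::is(table, "LocalisationTable"), renderPixelNm > 0)
  df <- table@records
  if (!nrow(df)) {
    out <- array(0, c(1L, 1L))
    attr(out, "renderPixelNm") <- renderPixelNm
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (is.null(extentNm)) extentNm <- max(df$x, df$y)
  npx <- max(1L, ceiling(extentNm / renderPixelNm))
  ix <- pmin(pmax(floor(df$x / renderPixelNm), 0), npx - 1L)
  iy <- pmin(pmax(floor(df$y / renderPixelNm), 0), npx - 1L)
  out <- array(tabulate(ix * npx + iy + 1L, nbins = npx * npx), c(npx, npx))
  if (blurSigmaPx > 0) out <- gaussSmooth(out, blurSigmaPx,
                                          2L * ceiling(3 * blurSigmaPx) + 1L)
  attr(out, "renderPixelNm") <- renderPixelNm
  attr(out, "flagged") <- FALSE
  out
}

#' Extract localisations from a reconstructed image
#'
#' Candidates are strict local maxima within a `(2r+1)^2` neighbourhood
#' whose value reaches `thresholdFraction` of the image maximum.  Each
#' candidate's position is the intensity-weighted centroid over its window,
#' converted to nm with the pixel-centre convention
#' (`x_nm = (col + 0.5) * pixelSizeNm`), and its intensity is the window
#' sum.
#'
#' @param reconstruction non-negative 2D matrix.
#' @param pixelSizeNm pixel pitch of the reconstruction (nm).
#' @param thresholdFraction detection threshold as a fraction of the image
#'   maximum (default 0.2).
#' @param windowRadiusPx neighbourhood/centroid window radius in pixels.
#' @return a [LocalisationTable-class] (all records on frame 1; the
#'   `photons` column holds the window-summed intensity).
#' @export
extractLocalisations <- function(reconstruction, pixelSizeNm,
                                 thresholdFraction = 0.2,
                                 windowRadiusPx = 3L) {
  stopifnot(is.matrix(reconstruction), pixelSizeNm > 0,
            thresholdFraction > 0, windowRadiusPx >= 1L)
  if (min(reconstruction) < 0) stop("reconstruction must be non-negative")
  mx <- max(reconstruction)
  empty <- LocalisationTable(data.frame(frame = numeric(), x = numeric(),
                                        y = numeric(), photons = numeric(),
                                        sigma = numeric()))
  if (mx == 0) return(empty)
  h <- nrow(reconstruction); w <- ncol(reconstruction)
  r <- as.integer(windowRadiusPx)
  thr <- thresholdFraction * mx
  cand <- which(reconstruction >= thr, arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    ri <- max(1L, i - r):min(h, i + r)
    rj <- max(1L, j - r):min(w, j + r)
    win <- reconstruction[ri, rj, drop = FALSE]
    v <- reconstruction[i, j]
    # strict local maximum: larger than every other pixel in the window
    if (sum(win == max(win)) > 1L || v < max(win)) next
    wsum <- sum(win)
    cy <- sum(win * (ri - 1)) / wsum       # weighted 0-based row index
    cx <- sum(t(win) * (rj - 1)) / wsum    # weighted 0-based col index
    rows[[length(rows) + 1L]] <- data.frame(
      frame = 1, x = (cx + 0.5) * pixelSizeNm, y = (cy + 0.5) * pixelSizeNm,
      photons = wsum, sigma = NA_real_)
  }
  if (!length(rows)) return(empty)
  LocalisationTable(do.call(rbind, rows))
}

#' Merge emission events split across consecutive frames
#'
#' A localisation in frame `f` joins an open track whose last position is
#' within `radiusNm` and whose last frame is at least `f - 1 -
#' maxDarkFrames` (so the default `maxDarkFrames = 0` forbids gaps —
#' "no dark frame allowed").  Assignment within a frame is
#' nearest-neighbour and one-to-one, ties broken toward the
#' earliest-created track.  Every finished track emits a single record with
#' the photon-weighted mean position, summed photons, photon-weighted mean
#' sigma, the first frame, and a `detections` count.
#'
#' @param table a [LocalisationTable-class].
#' @param radiusNm linking distance in nm (default 40).
#' @param maxDarkFrames allowed dark-frame gap (default 0).
#' @return a merged [LocalisationTable-class]; one row per track.
#' @export
mergeEvents <- function(table, radiusNm = 40, maxDarkFrames = 0L) {
  stopifnot(methods::is(table, "LocalisationTable"), radiusNm > 0,
            maxDarkFrames >= 0L)
  df <- table@records[order(table@records$frame), , drop = FALSE]
  if (!nrow(df)) return(table)
  w <- df$photons
  w[is.na(w) | w <= 0] <- 1   # unweighted fallback for photon-less records
  tr <- list(x = numeric(), y = numeric(), lastFrame = numeric(),
             firstFrame = numeric(), sx = numeric(), sy = numeric(),
             sw = numeric(), photons = numeric(), ssig = numeric(),
             n = integer())
  for (f in sort(unique(df$frame))) {
    idx <- which(df$frame == f)
    open <- which(tr$lastFrame >= f - 1 - maxDarkFrames & tr$lastFrame < f)
    assigned <- rep(NA_integer_, length(idx))
    if (length(open)) {
      d <- outer(seq_along(idx), seq_along(open), function(a, b) {
        sqrt((df$x[idx[a]] - tr$x[open[b]])^2 +
             (df$y[idx[a]] - tr$y[open[b]])^2)
      })
      d[d > radiusNm] <- Inf
      while (any(is.finite(d))) {
        best <- which(d == min(d), arr.ind = TRUE)
        # tie-break toward the earliest-created track
        best <- best[order(open[best[, 2L]]), , drop = FALSE][1L, ]
        assigned[best[1L]] <- open[best[2L]]
        d[best[1L], ] <- Inf
        d[, best[2L]] <- Inf
      }
    }
    for (a in seq_along(idx)) {
      i <- idx[a]
      sig <- if (is.na(df$sigma[i])) 0 else df$sigma[i]
      if (is.na(assigned[a])) {
        tr$x <- c(tr$x, df$x[i]); tr$y <- c(tr$y, df$y[i])
        tr$lastFrame <- c(tr$lastFrame, f)
        tr$firstFrame <- c(tr$firstFrame, f)
        tr$sx <- c(tr$sx, w[i] * df$x[i]); tr$sy <- c(tr$sy, w[i] * df$y[i])
        tr$sw <- c(tr$sw, w[i])
        tr$photons <- c(tr$photons, ifelse(is.na(df$photons[i]), 0,
                                           df$photons[i]))
        tr$ssig <- c(tr$ssig, w[i] * sig)
        tr$n <- c(tr$n, 1L)
      } else {
        t <- assigned[a]
        tr$sx[t] <- tr$sx[t] + w[i] * df$x[i]
        tr$sy[t] <- tr$sy[t] + w[i] * df$y[i]
        tr$sw[t] <- tr$sw[t] + w[i]
        tr$photons[t] <- tr$photons[t] +
          ifelse(is.na(df$photons[i]), 0, df$photons[i])
        tr$ssig[t] <- tr$ssig[t] + w[i] * sig
        tr$x[t] <- tr$sx[t] / tr$sw[t]
        tr$y[t] <- tr$sy[t] / tr$sw[t]
        tr$lastFrame[t] <- f
        tr$n[t] <- tr$n[t] + 1L
      }
    }
  }
  out <- data.frame(frame = tr$firstFrame, x = tr$sx / tr$sw,
                    y = tr$sy / tr$sw, photons = tr$photons,
                    sigma = ifelse(tr$ssig > 0, tr$ssig / tr$sw, NA_real_),
                    detections = tr$n)
  out <- out[order(out$frame), , drop = FALSE]
  LocalisationTable(out)
}

# circular cross-correlation shift of img vs ref with 3x3 centroid
# sub-pixel refinement; positive shift means img displaced toward larger
# indices relative to ref
ccShift <- function(ref, img) {
  n <- nrow(ref)
  cc <- Re(stats::fft(Conj(stats::fft(ref)) * stats::fft(img),
                      inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  sub <- function(di, dj) {
    cc[(pk[1L] - 1L + di) %% n + 1L, (pk[2L] - 1L + dj) %% n + 1L]
  }
  w <- outer(-1:1, -1:1, Vectorize(sub))
  w <- w - min(w)
  off <- if (sum(w) > 0) {
    c(sum(w * matrix(-1:1, 3, 3)) / sum(w),
      sum(w * matrix(-1:1, 3, 3, byrow = TRUE)) / sum(w))
  } else c(0, 0)
  raw <- pk - 1L
  raw <- ifelse(raw > n / 2, raw - n, raw)
  raw + off   # (row shift, col shift)
}

#' Estimate drift by cross-correlation of time-binned renderings
#'
#' Splits the table into `nTimeBins` temporal bins of (approximately) equal
#' localisation count, renders each with [renderHistogram()] on a common
#' grid, and measures the displacement of every bin relative to the first
#' from the cross-correlation peak with 3x3-centroid sub-pixel refinement.
#' The per-frame trace interpolates linearly between bin centres and is
#' anchored at exactly (0, 0) for frame 1.
#'
#' @param table a [LocalisationTable-class] spanning at least `nTimeBins`
#'   frames.
#' @param nTimeBins number of temporal bins (>= 2).
#' @param renderPixelNm rendering pitch for the correlation images (nm).
#' @return a `DriftTrace`: data frame with columns `frame`, `dx`, `dy` (nm,
#'   displacement relative to frame 1), one row per frame, and a `bins`
#'   attribute with per-bin shifts, counts and a low-confidence flag for
#'   bins under 10 localisations.
#' @export
estimateDrift <- function(table, nTimeBins, renderPixelNm) {
  stopifnot(methods::is(table, "LocalisationTable"), nTimeBins >= 2L)
  df <- table@records[order(table@records$frame), , drop = FALSE]
  if (length(unique(df$frame)) < nTimeBins) {
    stop("table must span at least nTimeBins distinct frames")
  }
  n <- nrow(df)
  bin <- ceiling(seq_len(n) * nTimeBins / n)
  extent <- max(df$x, df$y)
  render <- function(rows) {
    renderHistogram(LocalisationTable(df[rows, , drop = FALSE]),
                    renderPixelNm, blurSigmaPx = 1, extentNm = extent)
  }
  ref <- render(bin == 1L)
  bins <- data.frame(bin = seq_len(nTimeBins), centre_frame = NA_real_,
                     dx = 0, dy = 0, n = NA_integer_, flagged = FALSE)
  for (k in seq_len(nTimeBins)) {
    rows <- bin == k
    bins$centre_frame[k] <- mean(df$frame[rows])
    bins$n[k] <- sum(rows)
    bins$flagged[k] <- sum(rows) < 10L
    if (k > 1L) {
      sh <- ccShift(ref, render(rows))
      bins$dy[k] <- sh[1L] * renderPixelNm
      bins$dx[k] <- sh[2L] * renderPixelNm
    }
  }
  maxFrame <- max(df$frame)
  frames <- seq_len(maxFrame)
  # linear interpolation between bin centres, linear extrapolation beyond
  # the first/last centre, then re-anchoring so frame 1 is exactly (0, 0)
  interpExtrap <- function(fx, fy) {
    y <- stats::approx(fx, fy, xout = frames, rule = 2, ties = mean)$y
    k <- length(fx)
    lo <- frames < fx[1L]
    hi <- frames > fx[k]
    s1 <- (fy[2L] - fy[1L]) / (fx[2L] - fx[1L])
    sk <- (fy[k] - fy[k - 1L]) / (fx[k] - fx[k - 1L])
    y[lo] <- fy[1L] + s1 * (frames[lo] - fx[1L])
    y[hi] <- fy[k] + sk * (frames[hi] - fx[k])
    y - (fy[1L] + s1 * (1 - fx[1L]))
  }
  dx <- interpExtrap(bins$centre_frame, bins$dx)
  dy <- interpExtrap(bins$centre_frame, bins$dy)
  trace <- data.frame(frame = frames, dx = dx - dx[1L], dy = dy - dy[1L])
  attr(trace, "bins") <- bins
  class(trace) <- c("DriftTrace", "data.frame")
  trace
}

#' Subtract a drift trace from a localisation table
#'
#' Each record's coordinates are reduced by its frame's displacement; all
#' other columns are unchanged.  Applying a trace and then its negation is
#' the identity.
#'
#' @param table a [LocalisationTable-class].
#' @param trace a `DriftTrace` (data frame with `frame`, `dx`, `dy`)
#'   covering every frame present in the table.
#' @return the drift-corrected [LocalisationTable-class].
#' @export
applyDrift <- function(table, trace) {
  stopifnot(methods::is(table, "LocalisationTable"))
  df <- table@records
  m <- match(df$frame, trace$frame)
  if (anyNA(m) && nrow(df)) {
    stop("trace does not cover frame(s): ",
         paste(sort(unique(df$frame[is.na(m)])), collapse = ", "))
  }
  df$x <- df$x - trace$dx[m]
  df$y <- df$y - trace$dy[m]
  LocalisationTable(df)
}

#' Negate a drift trace
#'
#' @param trace a `DriftTrace`.
#' @return the element-wise negated trace.
#' @export
negateDrift <- function(trace) {
  trace$dx <- -trace$dx
  trace$dy <- -trace$dy
  trace
}
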