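# Restoration / image-translation quality control: percentile normalisation,
# least-squares affine intensity matching, SSIM maps + mSSIM, RSE maps +
# NRMSE, PSNR, and the combined target-vs-source / target-vs-prediction
# report used to judge whether a model improved on its input.

#' Percentile-normalise an image
#'
#' Maps the `pmin` percentile to 0 and the `pmax` percentile to 1 without
#' clipping; robust to hot pixels at the default 1/99.9 percentiles.  A
#' constant image maps to all zeros (degenerate branch).
#'
#' @param image 2D numeric matrix.
#' @param pmin,pmax lower/upper percentiles in `[0, 100]`, `pmin < pmax`.
#' @return normalised matrix with attributes `pmin`, `pmax`.
#' @export
percentileNormalize <- function(image, pmin = 1, pmax = 99.9) {
  stopifnot(is.matrix(image), pmin < pmax, pmin >= 0, pmax <= 100)
  q <- stats::quantile(image, c(pmin, pmax) / 100, names = FALSE)
  out <- if (q[2L] > q[1L]) (image - q[1L]) / (q[2L] - q[1L])
         else array(0, dim(image))
  attr(out, "pmin") <- pmin
  attr(out, "pmax") <- pmax
  out
}

#' Least-squares affine intensity match
#'
#' Returns `alpha * image + beta` with `(alpha, beta)` the closed-form
#' least-squares minimisers of the mean squared error to `reference`.  Makes
#' the downstream metrics invariant to affine intensity rescaling of the
#' comparison image.  A zero-variance image cannot be matched; it is mapped
#' to the constant `mean(reference)` and flagged.
#'
#' @param reference,image 2D matrices of identical shape.
#' @return matched matrix with attributes `alpha`, `beta`, `flagged`.
#' @export
affineMatch <- function(reference, image) {
  stopIfShapeMismatch(reference, image)
  vx <- stats::var(as.vector(image))
  if (vx == 0) {
    out <- array(mean(reference), dim(reference))
    attr(out, "alpha") <- 0
    attr(out, "beta") <- mean(reference)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  alpha <- stats::cov(as.vector(image), as.vector(reference)) / vx
  beta <- mean(reference) - alpha * mean(image)
  out <- alpha * image + beta
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  attr(out, "flagged") <- FALSE
  out
}

#' SSIM parameter set
#'
#' Standard structural-similarity constants: stabilisers `C1 = (K1*L)^2`,
#' `C2 = (K2*L)^2` with `K1 = 0.01`, `K2 = 0.03`, data range `L = 1` on
#' normalised inputs, and an 11-pixel Gaussian window of sigma 1.5.
#'
#' @param K1,K2 stabilisation fractions (> 0).
#' @param L data range of the (normalised) inputs.
#' @param windowSigma Gaussian window sd in pixels.
#' @param windowSize odd window span in pixels (>= 3).
#' @return a list with the parameters and derived `C1`, `C2`.
#' @export
ssimParams <- function(K1 = 0.01, K2 = 0.03, L = 1, windowSigma = 1.5,
                       windowSize = 11L) {
  stopifnot(K1 > 0, K2 > 0, L > 0, windowSize %% 2L == 1L, windowSize >= 3L)
  list(K1 = K1, K2 = K2, L = L, windowSigma = windowSigma,
       windowSize = as.integer(windowSize),
       C1 = (K1 * L)^2, C2 = (K2 * L)^2)
}

#' Per-pixel SSIM map and mean SSIM
#'
#' Local luminance/contrast/structure comparison with Gaussian-weighted
#' means, variances and covariance computed over a sliding window
#' (replicated borders).  The map lies in `[-1, 1]`; `mssim` is its mean and
#' equals 1 only for identical inputs.
#'
#' @param reference,image 2D matrices of identical shape, already normalised.
#' @param params see [ssimParams()].
#' @return list with `map` (matrix) and `mssim` (scalar).
#' @export
ssimMap <- function(reference, image, params = ssimParams()) {
  stopIfShapeMismatch(reference, image)
  sm <- function(z) gaussSmooth(z, params$windowSigma, params$windowSize)
  mu1 <- sm(reference)
  mu2 <- sm(image)
  s11 <- sm(reference * reference) - mu1 * mu1
  s22 <- sm(image * image) - mu2 * mu2
  s12 <- sm(reference * image) - mu1 * mu2
  C1 <- params$C1; C2 <- params$C2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  map <- pmin(pmax(map, -1), 1)
  list(map = map, mssim = mean(map))
}

#' Root-squared-error map and NRMSE
#'
#' The map is the per-pixel absolute difference of the (normalised) images;
#' NRMSE is the root-mean-squared error divided by a normaliser of the
#' reference: its standard deviation (default), its value range, or its
#' mean.
#'
#' @param reference,image 2D matrices of identical shape, normalised.
#' @param mode NRMSE denominator: `"sd"`, `"range"` or `"mean"`.
#' @return list with `map`, `nrmse`, `mode` and `flagged` (TRUE when the
#'   denominator is degenerate and `nrmse` is `NA`).
#' @export
rseMap <- function(reference, image, mode = c("sd", "range", "mean")) {
  mode <- match.arg(mode)
  stopIfShapeMismatch(reference, image)
  map <- abs(reference - image)
  rmse <- sqrt(mean((reference - image)^2))
  denom <- switch(mode,
    sd = stats::sd(as.vector(reference)) *
         sqrt((length(reference) - 1) / length(reference)),
    range = diff(range(reference)),
    mean = mean(reference))
  if (!is.finite(denom) || denom <= 0) {
    return(list(map = map, nrmse = NA_real_, mode = mode, flagged = TRUE))
  }
  list(map = map, nrmse = rmse / denom, mode = mode, flagged = FALSE)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `20*log10(L) - 10*log10(MSE)`.  Identical images have infinite PSNR,
#' reported as `Inf` with the `flagged` attribute set.
#'
#' @param reference,image 2D matrices of identical shape, normalised.
#' @param L data range (1 for percentile-normalised inputs).
#' @return PSNR in dB (possibly `Inf`, flagged).
#' @export
psnr <- function(reference, image, L = 1) {
  stopIfShapeMismatch(reference, image)
  mse <- mean((reference - image)^2)
  out <- if (mse == 0) Inf else 20 * log10(L) - 10 * log10(mse)
  attr(out, "flagged") <- !is.finite(out)
  out
}

#' Full restoration QC report
#'
#' Normalises the target by percentiles, affine-matches source and
#' prediction onto it, and computes mSSIM / NRMSE / PSNR for both
#' target-vs-source and target-vs-prediction, plus the per-pixel SSIM and
#' RSE maps for the prediction comparison.  The prediction is judged an
#' improvement when `mssim_tp > mssim_ts` and `nrmse_tp < nrmse_ts`.
#'
#' 3D stacks are scored slice-wise: scalars are averaged over slices and the
#' maps of each slice are returned as stacks.
#'
#' @param source,target,prediction matrices (or [ImageStack-class] objects /
#'   3D arrays of identical shape).
#' @param params SSIM parameters, see [ssimParams()].
#' @param pmin,pmax target normalisation percentiles.
#' @param nrmseMode NRMSE denominator mode, see [rseMap()].
#' @return list of class `"RestorationReport"` with fields `mssim_ts`,
#'   `nrmse_ts`, `psnr_ts`, `mssim_tp`, `nrmse_tp`, `psnr_tp`, `ssim_map`,
#'   `rse_map`, `improved`, and the configuration used.
#' @export
restorationReport <- function(source, target, prediction,
                              params = ssimParams(), pmin = 1, pmax = 99.9,
                              nrmseMode = "sd") {
  asArr <- function(z) {
    if (methods::is(z, "ImageStack")) z@data
    else if (is.matrix(z)) array(z, c(dim(z), 1L)) else z
  }
  src <- asArr(source); tgt <- asArr(target); prd <- asArr(prediction)
  stopIfShapeMismatch(tgt, src)
  stopIfShapeMismatch(tgt, prd)
  n <- dim(tgt)[3L]
  per <- lapply(seq_len(n), function(i) {
    tn <- percentileNormalize(tgt[, , i], pmin, pmax)
    sn <- affineMatch(tn, src[, , i])
    pn <- affineMatch(tn, prd[, , i])
    sTS <- ssimMap(tn, sn, params); sTP <- ssimMap(tn, pn, params)
    rTS <- rseMap(tn, sn, nrmseMode); rTP <- rseMap(tn, pn, nrmseMode)
    list(mssim_ts = sTS$mssim, nrmse_ts = rTS$nrmse,
         psnr_ts = as.numeric(psnr(tn, sn, params$L)),
         mssim_tp = sTP$mssim, nrmse_tp = rTP$nrmse,
         psnr_tp = as.numeric(psnr(tn, pn, params$L)),
         ssim_map = sTP$map, rse_map = rTP$map)
  })
  sc <- function(f) mean(vapply(per, `[[`, numeric(1L), f))
  maps <- function(f) {
    a <- array(unlist(lapply(per, `[[`, f)), dim = dim(tgt))
    if (n == 1L) a[, , 1L] else a
  }
  rep <- list(mssim_ts = sc("mssim_ts"), nrmse_ts = sc("nrmse_ts"),
              psnr_ts = sc("psnr_ts"), mssim_tp = sc("mssim_tp"),
              nrmse_tp = sc("nrmse_tp"), psnr_tp = sc("psnr_tp"),
              ssim_map = maps("ssim_map"), rse_map = maps("rse_map"),
              config = list(pmin = pmin, pmax = pmax, nrmse_mode = nrmseMode,
                            K1 = params$K1, K2 = params$K2, L = params$L,
                            window_sigma = params$windowSigma,
                            window_size = params$windowSize))
  rep$improved <- rep$mssim_tp > rep$mssim_ts && rep$nrmse_tp < rep$nrmse_ts
  class(rep) <- "RestorationReport"
  rep
}

#' @export
print.RestorationReport <- function(x, ...) {
  cat("Restoration QC report\n")
  cat(sprintf("  target vs source:     mSSIM %.4f  NRMSE %.4f  PSNR %.2f dB\n",
              x$mssim_ts, x$nrmse_ts, x$psnr_ts))
  cat(sprintf("  target vs prediction: mSSIM %.4f  NRMSE %.4f  PSNR %.2f dB\n",
              x$mssim_tp, x$nrmse_tp, x$psnr_tp))
  cat(sprintf("  prediction improves on source: %s\n",
              if (x$improved) "yes" else "no"))
  invisible(x)
}
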