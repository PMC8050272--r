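# SMLM training-data simulator: per-frame emitter sampling, pixel-integrated
# Gaussian PSF rendering, and a Poisson shot-noise + Gaussian read-noise
# camera model with gain and baseline offset.

#' Bundled simulator parameter presets
#'
#' Parameter sets matching experimentally calibrated high-density dSTORM
#' acquisitions of the actin cytoskeleton ("bin4", "bin10": the same raw
#' movie sum-binned in groups of 4 or 10 frames) and of microtubules
#' ("tubulin").
#'
#' @param name `"bin4"`, `"bin10"` or `"tubulin"`.
#' @param seed RNG seed stored in the preset.
#' @return a [SimulationParameters-class].
#' @export
simulationPreset <- function(name = c("bin4", "bin10", "tubulin"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    bin4 = SimulationParameters(
      fovSizeNm = 10240, pixelSizeNm = 160, adcPerPhoton = 16,
      readoutNoiseAdc = 1040, offsetAdc = 10550, densityMean = 2.8,
      densityStd = 0, nFrames = 20, psfSigmaNm = 153, psfSigmaStdNm = 29,
      photonsMean = 3500, photonsStd = 850, seed = seed),
    bin10 = SimulationParameters(
      fovSizeNm = 10240, pixelSizeNm = 160, adcPerPhoton = 16,
      readoutNoiseAdc = 1800, offsetAdc = 26500, densityMean = 4,
      densityStd = 0.8, nFrames = 20, psfSigmaNm = 150, psfSigmaStdNm = 25,
      photonsMean = 5500, photonsStd = 2000, seed = seed),
    tubulin = SimulationParameters(
      fovSizeNm = 15800, pixelSizeNm = 158, adcPerPhoton = 12.7,
      readoutNoiseAdc = 370, offsetAdc = 4090, densityMean = 3,
      densityStd = 0.5, nFrames = 20, psfSigmaNm = 160, psfSigmaStdNm = 30,
      photonsMean = 2800, photonsStd = 900, seed = seed))
}

# add one pixel-integrated 2D Gaussian (photons total mass) to `img`;
# x/y in nm, pixel pitch p, truncated past 4 sigma
addSpot <- function(img, x, y, photons, sigma, p) {
  h <- nrow(img); w <- ncol(img)
  c0 <- max(0L, floor((x - 4 * sigma) / p))
  c1 <- min(w - 1L, ceiling((x + 4 * sigma) / p))
  r0 <- max(0L, floor((y - 4 * sigma) / p))
  r1 <- min(h - 1L, ceiling((y + 4 * sigma) / p))
  if (c1 < c0 || r1 < r0) return(img)
  cols <- c0:c1
  rows <- r0:r1
  fx <- stats::pnorm(((cols + 1) * p - x) / sigma) -
        stats::pnorm((cols * p - x) / sigma)
  fy <- stats::pnorm(((rows + 1) * p - y) / sigma) -
        stats::pnorm((rows * p - y) / sigma)
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    photons * outer(fy, fx)
  img
}

#' Simulate an SMLM acquisition
#'
#' Per frame, the number of active emitters is drawn as
#' `round(max(0, Normal(densityMean, densityStd)) * FOV area in um^2)` (or
#' Poisson with that mean via `densityLaw = "poisson"`); emitter positions
#' are uniform over the field of view, and each emitter draws its photon
#' count and PSF sigma from truncated (> 0) normal distributions.  The
#' expected photon image is the sum of pixel-integrated 2D Gaussians, and
#' the camera converts it to counts as
#' `ADU = offset + Poisson(photons) / gain + Normal(0, readNoise)`, clipped
#' at zero.  Emitters outside the FOV are not simulated (no wraparound); the
#' ground-truth table contains exactly the emitters that were rendered.
#' Identical seeds reproduce stacks and tables exactly.
#'
#' @param params a [SimulationParameters-class], e.g. from
#'   [simulationPreset()].
#' @param densityLaw `"normal"` (default) or `"poisson"` per-frame emitter
#'   count law.
#' @param invertedGain if `TRUE`, interpret the conversion factor as A/D
#'   counts per photoelectron (`ADU = photons * factor`) instead of the
#'   default photoelectrons-per-count convention.
#' @return list with `stack` (an [ImageStack-class], float32 camera counts)
#'   and `truth` (a [LocalisationTable-class]: frame, x, y in nm, photons,
#'   sigma).
#' @export
simulateStack <- function(params, densityLaw = c("normal", "poisson"),
                          invertedGain = FALSE) {
  densityLaw <- match.arg(densityLaw)
  stopifnot(methods::is(params, "SimulationParameters"))
  methods::validObject(params)
  p <- params@pixelSizeNm
  npx <- as.integer(round(params@fovSizeNm / p))
  areaUm2 <- (params@fovSizeNm / 1000)^2
  n <- as.integer(params@nFrames)
  withSeed(params@seed, {
    frames <- array(0, c(npx, npx, n))
    gt <- vector("list", n)
    for (f in seq_len(n)) {
      dens <- if (densityLaw == "poisson") {
        stats::rpois(1L, params@densityMean * areaUm2) / areaUm2
      } else if (params@densityStd > 0) {
        max(0, stats::rnorm(1L, params@densityMean, params@densityStd))
      } else {
        params@densityMean
      }
      nEm <- as.integer(round(dens * areaUm2))
      img <- array(0, c(npx, npx))
      if (nEm > 0L) {
        x <- stats::runif(nEm, 0, params@fovSizeNm)
        y <- stats::runif(nEm, 0, params@fovSizeNm)
        photons <- truncNorm(nEm, params@photonsMean, params@photonsStd)
        sigma <- truncNorm(nEm, params@psfSigmaNm, params@psfSigmaStdNm)
        for (e in seq_len(nEm)) {
          img <- addSpot(img, x[e], y[e], photons[e], sigma[e], p)
        }
        gt[[f]] <- data.frame(frame = f, x = x, y = y, photons = photons,
                              sigma = sigma)
      }
      shot <- stats::rpois(length(img), img)
      electronsToAdu <- if (invertedGain) params@adcPerPhoton
                        else 1 / params@adcPerPhoton
      adu <- params@offsetAdc + shot * electronsToAdu +
        stats::rnorm(length(img), 0, params@readoutNoiseAdc)
      frames[, , f] <- pmax(array(adu, dim(img)), 0)
    }
    gt <- Filter(Negate(is.null), gt)
    truth <- if (length(gt)) do.call(rbind, gt)
             else data.frame(frame = numeric(), x = numeric(), y = numeric(),
                             photons = numeric(), sigma = numeric())
    list(stack = ImageStack(frames, pixelSizeNm = p, dtype = "float32"),
         truth = LocalisationTable(truth))
  })
}
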