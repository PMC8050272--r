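test_that("simulator presets reproduce the calibrated acquisition settings", {
  p <- simulationPreset("bin4")
  expect_equal(p@densityMean, 2.8)
  expect_equal(p@nFrames, 20)
  expect_equal(p@fovSizeNm / p@pixelSizeNm, 64)
  expect_equal(simulationPreset("bin10")@offsetAdc, 26500)
  expect_equal(simulationPreset("tubulin")@adcPerPhoton, 12.7)
})

test_that("simulated stacks honour the density and frame-count contract", {
  sim <- simulateStack(simulationPreset("bin4", seed = 27))
  expect_identical(dim(sim$stack), c(64L, 64L, 20L))
  # density std 0: emitter count per frame is constant round(2.8 * 10.24^2)
  tr <- locRecords(sim$truth)
  perFrame <- table(tr$frame)
  expect_true(all(perFrame == round(2.8 * 10.24^2)))
  expect_length(perFrame, 20L)
  # every coordinate lies inside the FOV
  expect_true(all(tr$x >= 0 & tr$x <= 10240))
  expect_true(all(tr$photons > 0) && all(tr$sigma > 0))
})

test_that("identical seeds reproduce stacks and tables exactly", {
  a <- simulateStack(simulationPreset("bin10", seed = 28))
  b <- simulateStack(simulationPreset("bin10", seed = 28))
  expect_identical(a$stack@data, b$stack@data)
  expect_identical(locRecords(a$truth), locRecords(b$truth))
  c <- simulateStack(simulationPreset("bin10", seed = 29))
  expect_false(identical(a$stack@data, c$stack@data))
})

test_that("photon mass is conserved through the PSF and camera", {
  # one emitter mid-FOV, no spread in photons, no read noise, no offset
  p <- SimulationParameters(fovSizeNm = 3200, pixelSizeNm = 160,
                            adcPerPhoton = 1, readoutNoiseAdc = 0,
                            offsetAdc = 0, densityMean = 1 / (3.2^2),
                            densityStd = 0, nFrames = 20, psfSigmaNm = 150,
                            psfSigmaStdNm = 0, photonsMean = 3500,
                            photonsStd = 0, seed = 30)
  sim <- simulateStack(p)
  tr <- locRecords(sim$truth)
  expect_identical(nrow(tr), 20L)
  total <- sum(sim$stack@data)
  # independent closed form: each emitter deposits the mass of its Gaussian
  # inside the FOV window (no wraparound at the borders)
  inWindow <- function(c0, s) {
    pnorm((3200 - c0) / s) - pnorm((0 - c0) / s)
  }
  expected <- sum(tr$photons * inWindow(tr$x, tr$sigma) *
                    inWindow(tr$y, tr$sigma))
  # Poisson error bound over the whole stack
  expect_lt(abs(total - expected), 4 * sqrt(expected))
})

test_that("the camera model reproduces offset and read-noise moments", {
  p <- SimulationParameters(fovSizeNm = 10240, pixelSizeNm = 160,
                            adcPerPhoton = 16, readoutNoiseAdc = 1040,
                            offsetAdc = 10550, densityMean = 0,
                            densityStd = 0, nFrames = 20, psfSigmaNm = 153,
                            photonsMean = 3500, seed = 31)
  sim <- simulateStack(p)
  v <- as.vector(sim$stack@data)
  n <- length(v)
  se <- 1040 / sqrt(n)
  expect_lt(abs(mean(v) - 10550), 3 * se)
  expect_lt(abs(sd(v) - 1040) / 1040, 0.05)
  expect_identical(nrow(locRecords(sim$truth)), 0L)
})

test_that("ground-truth photon statistics and PSF width are recoverable", {
  # stds = 0: every ground-truth photon count equals the mean exactly
  p <- SimulationParameters(fovSizeNm = 10240, pixelSizeNm = 160,
                            adcPerPhoton = 1, readoutNoiseAdc = 0,
                            offsetAdc = 0, densityMean = 5, densityStd = 0,
                            nFrames = 20, psfSigmaNm = 153,
                            psfSigmaStdNm = 0, photonsMean = 3500,
                            photonsStd = 0, seed = 32)
  sim <- simulateStack(p)
  expect_true(all(locRecords(sim$truth)$photons == 3500))
  # moment-fitted sigma of noise-free bright spots within 2% of nominal;
  # only emitters far enough from the border for the full spot to render
  p2 <- SimulationParameters(fovSizeNm = 6400, pixelSizeNm = 160,
                             adcPerPhoton = 1, readoutNoiseAdc = 0,
                             offsetAdc = 0, densityMean = 1 / 6.4^2,
                             densityStd = 0, nFrames = 20, psfSigmaNm = 153,
                             psfSigmaStdNm = 0, photonsMean = 2e6,
                             photonsStd = 0, seed = 33)
  sim2 <- simulateStack(p2)
  tr <- locRecords(sim2$truth)
  inner <- pmin(tr$x, tr$y, 6400 - tr$x, 6400 - tr$y) > 5 * 153
  expect_gt(sum(inner), 2)
  sig <- vapply(which(inner), function(i) {
    img <- getFrame(sim2$stack, tr$frame[i])
    cols <- (seq_len(ncol(img)) - 0.5) * 160
    rows <- (seq_len(nrow(img)) - 0.5) * 160
    tot <- sum(img)
    mx <- sum(t(img) * cols) / tot
    vx <- sum(t(img) * (cols - mx)^2) / tot
    my <- sum(img * rows) / tot
    vy <- sum(img * (rows - my)^2) / tot
    # subtract the pixel-integration variance p^2/12
    sqrt((vx + vy) / 2 - 160^2 / 12)
  }, numeric(1))
  expect_lt(max(abs(sig - 153) / 153), 0.02)
})

test_that("histogram rendering conserves counts and bins correctly", {
  one <- LocalisationTable(frame = 1, x = 250, y = 130, photons = 1000)
  h <- renderHistogram(one, renderPixelNm = 100, extentNm = 500)
  expect_equal(sum(h), 1)
  expect_equal(h[2, 3], 1)   # y 130 -> row 2, x 250 -> col 3
  set.seed(34)
  tab <- LocalisationTable(frame = rep(1, 500), x = runif(500, 0, 1000),
                           y = runif(500, 0, 1000), photons = 1)
  h2 <- renderHistogram(tab, 50, extentNm = 1000)
  expect_equal(sum(h2), 500)
  # uniform table is compatible with a uniform law (chi-square)
  chi <- sum((h2 - mean(h2))^2 / mean(h2))
  expect_lt(chi, qchisq(1 - 0.001, length(h2) - 1))
  # empty table flagged
  empty <- LocalisationTable(data.frame(frame = numeric(), x = numeric(),
                                        y = numeric(), photons = numeric()))
  expect_true(attr(renderHistogram(empty, 10), "flagged"))
})

test_that("spot extraction recovers sub-pixel positions", {
  # a pixel-integrated Gaussian at a known sub-pixel position
  px <- 100
  img <- array(0, c(32, 32))
  x0 <- 14.3 * px; y0 <- 17.8 * px   # nm, pixel-centre convention
  img <- microQC:::addSpot(img, x0, y0, 1e4, 1.5 * px, px)
  tab <- extractLocalisations(img, px, thresholdFraction = 0.2,
                              windowRadiusPx = 5)
  expect_identical(length(tab), 1L)
  expect_lt(abs(locRecords(tab)$x - x0), 0.1 * px)
  expect_lt(abs(locRecords(tab)$y - y0), 0.1 * px)
  # two Gaussians 10 px apart give exactly two localisations
  img2 <- microQC:::addSpot(img, x0 + 10 * px, y0, 1e4, 1.5 * px, px)
  expect_identical(length(extractLocalisations(img2, px)), 2L)
  # flat sub-threshold image yields nothing
  expect_identical(length(extractLocalisations(array(0, c(16, 16)), px)), 0L)
})

test_that("event merging implements the gap-free linking rule", {
  # one emitter in frames 1-5 within 40 nm: a single merged record
  tab <- LocalisationTable(frame = 1:5, x = c(100, 110, 95, 105, 100),
                           y = rep(200, 5), photons = rep(500, 5))
  m <- mergeEvents(tab, radiusNm = 40, maxDarkFrames = 0)
  expect_identical(length(m), 1L)
  expect_equal(locRecords(m)$photons, 2500)
  expect_equal(locRecords(m)$frame, 1)
  expect_equal(locRecords(m)$x, mean(c(100, 110, 95, 105, 100)))
  # a missing frame breaks the track when no dark frames are allowed
  tab2 <- LocalisationTable(frame = c(1, 2, 4, 5), x = rep(100, 4),
                            y = rep(200, 4), photons = rep(500, 4))
  m2 <- mergeEvents(tab2, radiusNm = 40, maxDarkFrames = 0)
  expect_identical(length(m2), 2L)
  # allowing one dark frame re-joins it
  expect_identical(length(mergeEvents(tab2, 40, maxDarkFrames = 1)), 1L)
  # tiny radius on distinct positions is the identity (row count)
  sep <- LocalisationTable(frame = c(1, 2), x = c(0, 500), y = c(0, 0),
                           photons = c(1, 1))
  expect_identical(length(mergeEvents(sep, radiusNm = 1e-6)), 2L)
})

test_that("merging well-separated blinking emitters equals union-find", {
  set.seed(35)
  nEm <- 50L
  # emitters on a grid, >= 200 nm apart
  gx <- rep(seq(200, 1800, length.out = 8), 7)[1:nEm]
  gy <- rep(seq(200, 1800, length.out = 7), each = 8)[1:nEm]
  rows <- list()
  for (e in seq_len(nEm)) {
    span <- sample(2:5, 1)
    start <- sample(1:10, 1)
    for (f in start:(start + span - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, x = gx[e] + rnorm(1, 0, 5), y = gy[e] + rnorm(1, 0, 5),
        photons = 800, sigma = 150)
    }
  }
  tab <- LocalisationTable(do.call(rbind, rows))
  m <- mergeEvents(tab, radiusNm = 40, maxDarkFrames = 0)
  expect_identical(length(m), nEm)
  df <- locRecords(tab)
  expect_equal(unionFindClusters(df$x, df$y, 40), nEm)
})

test_that("drift estimation recovers synthetic linear drift", {
  d <- makeDriftedLocalisations(seed = 36)
  trace <- estimateDrift(d$table, nTimeBins = 5, renderPixelNm = 20)
  # anchoring contract
  expect_identical(trace$dx[1], 0)
  expect_identical(trace$dy[1], 0)
  tol <- max(0.5 * 20, 10)
  n <- nrow(trace)
  expect_lt(abs(trace$dx[n] - d$trueDrift$dx[n]), tol)
  expect_lt(abs(trace$dy[n] - d$trueDrift$dy[n]), tol)
  # zero drift estimates within half a rendering pixel
  d0 <- makeDriftedLocalisations(driftNm = c(0, 0), seed = 37)
  t0 <- estimateDrift(d0$table, 5, 20)
  expect_lt(max(abs(c(t0$dx, t0$dy))), 10)
})

test_that("applying drift corrections is exact and reduces residual drift", {
  d <- makeDriftedLocalisations(seed = 38)
  trace <- estimateDrift(d$table, 5, 20)
  corr <- applyDrift(d$table, trace)
  # apply then apply the negated trace restores the table
  back <- applyDrift(corr, negateDrift(trace))
  expect_equal(locRecords(back)$x, locRecords(d$table)$x, tolerance = 1e-9)
  # zero trace is the identity
  zero <- trace; zero$dx <- 0; zero$dy <- 0
  expect_equal(locRecords(applyDrift(d$table, zero)),
               locRecords(d$table))
  # residual drift after correction is far smaller than before
  res <- estimateDrift(corr, 5, 20)
  endBefore <- sqrt(trace$dx[100]^2 + trace$dy[100]^2)
  endAfter <- sqrt(res$dx[100]^2 + res$dy[100]^2)
  expect_lt(endAfter, endBefore / 3)
  # frames outside the trace are rejected
  expect_error(applyDrift(d$table, trace[1:50, ]), "cover")
})

test_that("the full localisation pipeline reduces positional error", {
  # simulate sparse frames, inject known drift, reconstruct per frame,
  # then merge and drift-correct; RMS deviation from the emitter layout
  # must shrink
  set.seed(39)
  nEm <- 25
  ex <- runif(nEm, 500, 4500); ey <- runif(nEm, 500, 4500)
  nFr <- 60
  drift <- cbind(seq(0, 120, length.out = nFr), seq(0, -80, length.out = nFr))
  rows <- lapply(seq_len(nFr), function(f) {
    data.frame(frame = f, x = ex + drift[f, 1] + rnorm(nEm, 0, 6),
               y = ey + drift[f, 2] + rnorm(nEm, 0, 6),
               photons = 1000, sigma = 150)
  })
  tab <- LocalisationTable(do.call(rbind, rows))
  rmsToLayout <- function(t) {
    df <- locRecords(t)
    sqrt(mean(vapply(seq_len(nrow(df)), function(i) {
      min((df$x[i] - ex)^2 + (df$y[i] - ey)^2)
    }, numeric(1))))
  }
  trace <- estimateDrift(tab, 6, 20)
  corrected <- applyDrift(tab, trace)
  expect_lt(rmsToLayout(corrected), rmsToLayout(tab) / 2)
})
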