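# internal helpers shared across modules

# run expr under a fixed RNG state without disturbing the caller's stream
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# normalised 1D Gaussian kernel; length forced odd
gaussKernel1d <- function(sigma, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  stopifnot(size %% 2L == 1L, size >= 1L)
  if (sigma <= 0) {
    k <- numeric(size)
    k[(size + 1L) / 2L] <- 1
    return(k)
  }
  r <- (size - 1L) / 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 2D filtering with replicate ("nearest") border handling; `kernel` is a
# full 2D kernel with odd dimensions
filter2Replicate <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

# local Gaussian-weighted smoothing used by the SSIM machinery
gaussSmooth <- function(img, sigma, size) {
  k1 <- gaussKernel1d(sigma, size)
  filter2Replicate(img, outer(k1, k1))
}

# draw from Normal(mean, sd) truncated to > 0 by resampling; after
# maxTries rejections the remaining draws are clamped at zero
truncNorm <- function(n, mean, sd, maxTries = 100L) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean <= 0) stop("degenerate truncated normal: mean <= 0 with sd = 0")
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(maxTries)) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, 0)
}

# match.arg-like check with a friendlier error
checkChoice <- function(value, choices, what) {
  if (!value %in% choices) {
    stop(sprintf("%s must be one of: %s", what, paste(choices, collapse = ", ")))
  }
  value
}

stopIfShapeMismatch <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share the same shape (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}
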