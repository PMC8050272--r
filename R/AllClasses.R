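# Core S4 containers.
#
# Coordinate convention used throughout the package: pixel indices are
# 0-based with half-open extents, and the physical position of a pixel is its
# centre, x_nm = (col + 0.5) * pixel_size_nm (likewise rows/y).  This keeps
# simulate -> render -> extract round trips free of half-pixel bias.

#' ImageStack: an ordered sequence of 2D grey-scale frames
#'
#' The universal image carrier of the package.  Frames are stored as a
#' 3-dimensional array `[height, width, frame]`; all frames share the same
#' spatial shape.  An optional physical pixel pitch (nm) travels with the
#' data so that downstream tools (centroid export, SMLM rendering) can
#' convert pixels to nanometres.
#'
#' @slot data numeric array of dimension `c(height, width, n_frames)`.
#' @slot pixelSizeNm physical pixel pitch in nm, or `NA_real_` when unknown.
#' @slot dtype storage precision tag, one of `"uint8"`, `"uint16"`,
#'   `"float32"`; controls how [writeImageStack()] encodes the data.
#'
#' @seealso [ImageStack()], [readImageStack()], [writeImageStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  slots = c(data = "array", pixelSizeNm = "numeric", dtype = "character"),
  prototype = prototype(pixelSizeNm = NA_real_, dtype = "float32")
)

setValidity("ImageStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) {
    return("data must be a 3D array [height, width, frame]")
  }
  if (d[3L] < 1L) {
    return("an ImageStack must contain at least one frame")
  }
  if (length(object@pixelSizeNm) != 1L) {
    return("pixelSizeNm must be a single value (NA allowed)")
  }
  if (!is.na(object@pixelSizeNm) && object@pixelSizeNm <= 0) {
    return("pixelSizeNm must be > 0 when set")
  }
  if (!object@dtype %in% c("uint8", "uint16", "float32")) {
    return("dtype must be one of 'uint8', 'uint16', 'float32'")
  }
  TRUE
})

#' Construct an ImageStack
#'
#' @param data a 2D matrix (promoted to a single-frame stack), a 3D array
#'   `[H, W, N]`, or a list of equally sized matrices.
#' @param pixelSizeNm physical pixel pitch in nm (optional).
#' @param dtype storage precision tag; guessed from the data when missing
#'   (integer-valued data in range become `"uint16"`, otherwise `"float32"`).
#' @return an [ImageStack-class] object.
#' @examples
#' s <- ImageStack(matrix(0, 8, 8), pixelSizeNm = 160)
#' nFrames(s)
#' @export
ImageStack <- function(data, pixelSizeNm = NA_real_, dtype = NULL) {
  if (is.list(data)) {
    stopifnot(length(data) >= 1L)
    d1 <- dim(data[[1L]])
    if (!all(vapply(data, function(m) identical(dim(m), d1), logical(1L)))) {
      stop("all frames must share the same height and width")
    }
    data <- array(unlist(data, use.names = FALSE), dim = c(d1, length(data)))
  }
  if (is.matrix(data)) {
    data <- array(data, dim = c(dim(data), 1L))
  }
  storage.mode(data) <- "double"
  if (is.null(dtype)) {
    mx <- suppressWarnings(max(data))
    dtype <- if (all(data == round(data)) && all(data >= 0) && mx <= 65535) {
      if (mx <= 255) "uint8" else "uint16"
    } else {
      "float32"
    }
  }
  methods::new("ImageStack", data = data,
               pixelSizeNm = as.numeric(pixelSizeNm), dtype = dtype)
}

#' @describeIn ImageStack number of frames
#' @param x,object an `ImageStack`
#' @export
nFrames <- function(x) dim(x@data)[3L]

#' @describeIn ImageStack extract frame `i` as a matrix
#' @param i frame index (1-based)
#' @export
getFrame <- function(x, i) {
  stopifnot(i >= 1L, i <= nFrames(x))
  x@data[, , i, drop = TRUE]
}

#' @describeIn ImageStack the pixel pitch in nm (`NA` when unknown)
#' @export
pixelSizeNm <- function(x) x@pixelSizeNm

#' @describeIn ImageStack frame dimensions `c(height, width, n_frames)`
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@data))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d frame(s) of %d x %d [%s]", d[3L], d[1L], d[2L],
              object@dtype))
  if (!is.na(object@pixelSizeNm)) {
    cat(sprintf(", pixel %.4g nm", object@pixelSizeNm))
  }
  cat("\n")
})

#' LocalisationTable: per-emitter records for SMLM work
#'
#' Wraps a data frame with at least the columns `frame` (1-based integer),
#' `x`, `y` (nm), `photons` and `sigma` (PSF width, nm; may be `NA`).  Extra
#' columns are carried through all operations verbatim.
#'
#' @slot records the underlying data frame.
#' @seealso [LocalisationTable()], [readLocalisations()], [mergeEvents()],
#'   [estimateDrift()]
#' @exportClass LocalisationTable
setClass("LocalisationTable", slots = c(records = "data.frame"))

setValidity("LocalisationTable", function(object) {
  df <- object@records
  need <- c("frame", "x", "y", "photons")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    return(paste("missing mandatory column(s):", paste(miss, collapse = ", ")))
  }
  if (nrow(df)) {
    if (any(df$frame < 1) || any(df$frame != round(df$frame))) {
      return("frame indices must be integers >= 1")
    }
    if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
      return("coordinates must be finite")
    }
    if (any(df$photons < 0, na.rm = TRUE)) {
      return("photons must be >= 0")
    }
  }
  TRUE
})

#' Construct a LocalisationTable
#'
#' @param frame 1-based acquisition frame per localisation, or a data frame
#'   holding all columns at once.
#' @param x,y emitter coordinates in nm.
#' @param photons photon count per localisation (>= 0).
#' @param sigma Gaussian PSF width in nm (optional, `NA` when unknown).
#' @param ... further per-localisation columns, preserved verbatim.
#' @return a [LocalisationTable-class].
#' @examples
#' LocalisationTable(frame = 1:2, x = c(100, 250), y = c(80, 90),
#'                   photons = c(1200, 900))
#' @export
LocalisationTable <- function(frame, x = NULL, y = NULL, photons = NULL,
                              sigma = NA_real_, ...) {
  if (is.data.frame(frame)) {
    df <- frame
    if (!"sigma" %in% names(df)) df$sigma <- rep(NA_real_, nrow(df))
    if (!"photons" %in% names(df)) df$photons <- rep(NA_real_, nrow(df))
  } else {
    df <- data.frame(frame = as.numeric(frame), x = as.numeric(x),
                     y = as.numeric(y), photons = as.numeric(photons),
                     sigma = as.numeric(sigma), ...)
  }
  rownames(df) <- NULL
  methods::new("LocalisationTable", records = df)
}

#' @describeIn LocalisationTable the underlying data frame
#' @param x,object a `LocalisationTable`
#' @export
locRecords <- function(x) x@records

#' @describeIn LocalisationTable number of localisations
#' @export
setMethod("length", "LocalisationTable", function(x) nrow(x@records))

setMethod("show", "LocalisationTable", function(object) {
  df <- object@records
  cat(sprintf("LocalisationTable: %d localisation(s)", nrow(df)))
  if (nrow(df)) {
    cat(sprintf(" over frames %d..%d", min(df$frame), max(df$frame)))
  }
  cat("\n")
  extra <- setdiff(names(df), c("frame", "x", "y", "photons", "sigma"))
  if (length(extra)) cat("  extra columns:", paste(extra, collapse = ", "), "\n")
})

#' SimulationParameters: SMLM simulator parameter block
#'
#' Holds the camera, PSF and photophysics parameters that drive
#' [simulateStack()].  Bundled presets matching published high-density
#' dSTORM acquisitions are available via [simulationPreset()].
#'
#' @slot fovSizeNm field-of-view side length (nm).
#' @slot pixelSizeNm camera pixel pitch (nm); must divide the FOV evenly.
#' @slot adcPerPhoton photoelectrons per A/D count; camera counts are
#'   `photons / adcPerPhoton` (set `invertedGain = TRUE` in
#'   [simulateStack()] for the reciprocal convention).
#' @slot readoutNoiseAdc Gaussian read-noise standard deviation (ADC counts).
#' @slot offsetAdc camera baseline offset (ADC counts).
#' @slot densityMean,densityStd per-frame emitter density mean / sd
#'   (emitters per um^2).
#' @slot nFrames number of frames to simulate.
#' @slot psfSigmaNm,psfSigmaStdNm per-emitter Gaussian PSF sigma mean / sd (nm).
#' @slot photonsMean,photonsStd per-emitter photon count mean / sd.
#' @slot seed RNG seed making the simulation fully reproducible.
#' @exportClass SimulationParameters
setClass("SimulationParameters",
  slots = c(fovSizeNm = "numeric", pixelSizeNm = "numeric",
            adcPerPhoton = "numeric", readoutNoiseAdc = "numeric",
            offsetAdc = "numeric", densityMean = "numeric",
            densityStd = "numeric", nFrames = "numeric",
            psfSigmaNm = "numeric", psfSigmaStdNm = "numeric",
            photonsMean = "numeric", photonsStd = "numeric",
            seed = "numeric")
)

setValidity("SimulationParameters", function(object) {
  pos <- c(fovSizeNm = object@fovSizeNm, pixelSizeNm = object@pixelSizeNm,
           adcPerPhoton = object@adcPerPhoton, nFrames = object@nFrames,
           psfSigmaNm = object@psfSigmaNm, photonsMean = object@photonsMean)
  if (any(pos <= 0)) {
    return(paste("must be > 0:", paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  nonneg <- c(readoutNoiseAdc = object@readoutNoiseAdc,
              offsetAdc = object@offsetAdc, densityMean = object@densityMean,
              densityStd = object@densityStd,
              psfSigmaStdNm = object@psfSigmaStdNm,
              photonsStd = object@photonsStd)
  if (any(nonneg < 0)) {
    return(paste("must be >= 0:",
                 paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  }
  npx <- object@fovSizeNm / object@pixelSizeNm
  if (abs(npx - round(npx)) > 1e-9) {
    return("fovSizeNm must divide into a whole number of pixels")
  }
  TRUE
})

#' Construct SMLM simulation parameters
#'
#' @param fovSizeNm field-of-view side (nm).
#' @param pixelSizeNm camera pixel size (nm).
#' @param adcPerPhoton photoelectrons per A/D count.
#' @param readoutNoiseAdc read noise sd (ADC counts).
#' @param offsetAdc camera offset (ADC counts).
#' @param densityMean,densityStd emitter density mean / sd (per um^2, per frame).
#' @param nFrames frame count.
#' @param psfSigmaNm,psfSigmaStdNm PSF sigma mean / per-emitter sd (nm).
#' @param photonsMean,photonsStd photons per emitter mean / sd.
#' @param seed RNG seed.
#' @return a [SimulationParameters-class].
#' @seealso [simulationPreset()] for ready-made parameter sets.
#' @export
SimulationParameters <- function(fovSizeNm = 10240, pixelSizeNm = 160,
                                 adcPerPhoton = 16, readoutNoiseAdc = 1040,
                                 offsetAdc = 10550, densityMean = 2.8,
                                 densityStd = 0, nFrames = 20,
                                 psfSigmaNm = 153, psfSigmaStdNm = 29,
                                 photonsMean = 3500, photonsStd = 850,
                                 seed = 1) {
  methods::new("SimulationParameters",
    fovSizeNm = fovSizeNm, pixelSizeNm = pixelSizeNm,
    adcPerPhoton = adcPerPhoton, readoutNoiseAdc = readoutNoiseAdc,
    offsetAdc = offsetAdc, densityMean = densityMean, densityStd = densityStd,
    nFrames = nFrames, psfSigmaNm = psfSigmaNm,
    psfSigmaStdNm = psfSigmaStdNm, photonsMean = photonsMean,
    photonsStd = photonsStd, seed = seed)
}

setMethod("show", "SimulationParameters", function(object) {
  cat(sprintf(
    "SimulationParameters: %g nm FOV @ %g nm px, %g frames\n",
    object@fovSizeNm, object@pixelSizeNm, object@nFrames))
  cat(sprintf("  density %g +/- %g /um^2, PSF sigma %g +/- %g nm\n",
              object@densityMean, object@densityStd, object@psfSigmaNm,
              object@psfSigmaStdNm))
  cat(sprintf("  photons %g +/- %g, camera gain %g e-/ADU, read %g, offset %g\n",
              object@photonsMean, object@photonsStd, object@adcPerPhoton,
              object@readoutNoiseAdc, object@offsetAdc))
})

#' DetectionSet: class-labelled bounding boxes for one image
#'
#' Boxes use 0-based half-open pixel coordinates internally
#' (`xmin <= x < xmax`); PASCAL VOC files, which are 1-based inclusive, are
#' converted on read/write by [readVOC()] and [writeVOC()].  Ground-truth
#' sets carry `NA` confidences.
#'
#' @slot imageName name of the image the boxes belong to.
#' @slot boxes data frame with columns `class`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, `confidence`.
#' @exportClass DetectionSet
setClass("DetectionSet",
  slots = c(imageName = "character", boxes = "data.frame"))

setValidity("DetectionSet", function(object) {
  b <- object@boxes
  need <- c("class", "xmin", "ymin", "xmax", "ymax", "confidence")
  if (!all(need %in% names(b))) {
    return(paste("boxes must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(b) && (any(b$xmax <= b$xmin) || any(b$ymax <= b$ymin))) {
    return("degenerate box: xmax must exceed xmin and ymax must exceed ymin")
  }
  if (nrow(b) && any(!is.na(b$confidence) &
                     (b$confidence < 0 | b$confidence > 1))) {
    return("confidence must lie in [0, 1]")
  }
  TRUE
})

#' Construct a DetectionSet
#'
#' @param imageName image identifier (unique within a dataset).
#' @param class character vector of class names, or a data frame of boxes.
#' @param xmin,ymin,xmax,ymax box corners, 0-based half-open pixels.
#' @param confidence detector scores in `[0, 1]`; `NA` for ground truth.
#' @return a [DetectionSet-class].
#' @export
DetectionSet <- function(imageName, class = character(), xmin = numeric(),
                         ymin = numeric(), xmax = numeric(),
                         ymax = numeric(), confidence = NA_real_) {
  if (is.data.frame(class)) {
    b <- class
    if (!"confidence" %in% names(b)) b$confidence <- NA_real_
  } else {
    n <- length(class)
    b <- data.frame(class = as.character(class),
                    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                    xmax = as.numeric(xmax), ymax = as.numeric(ymax),
                    confidence = rep_len(as.numeric(confidence), n))
  }
  rownames(b) <- NULL
  methods::new("DetectionSet", imageName = imageName, boxes = b)
}

#' @describeIn DetectionSet the box data frame
#' @param x,object a `DetectionSet`
#' @export
detBoxes <- function(x) x@boxes

#' @describeIn DetectionSet the image name
#' @export
detImageName <- function(x) x@imageName

setMethod("show", "DetectionSet", function(object) {
  b <- object@boxes
  cat(sprintf("DetectionSet '%s': %d box(es)", object@imageName, nrow(b)))
  if (nrow(b)) {
    cat(" [", paste(sort(unique(b$class)), collapse = ", "), "]", sep = "")
  }
  cat("\n")
})
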