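# Stack and localisation-table I/O plus stack utilities (frame binning,
# tiling, source/target pairing).

#' Read a (multi-page) TIFF file into an ImageStack
#'
#' Single- and multi-page grey-scale TIFFs are supported; pages become
#' frames in file order.  Integer data are returned at their stored scale
#' (e.g. 0..65535 for 16-bit) and IEEE-float pages verbatim.
#'
#' @param path path to a TIFF file.
#' @param pixelSizeNm optional physical pixel pitch (nm) to attach.
#' @return an [ImageStack-class].
#' @seealso [writeImageStack()]
#' @export
readImageStack <- function(path, pixelSizeNm = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      if (grepl("floating point", conditionMessage(e))) {
        return(tiff::readTIFF(path, all = TRUE))
      }
      stop("not a readable TIFF file: ", path, " (", conditionMessage(e), ")")
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1L)))) {
    stop("only single-channel grey-scale TIFFs are supported: ", path)
  }
  asis <- all(vapply(pages, function(p) all(p == round(p)), logical(1L)))
  dtype <- if (!asis) {
    "float32"
  } else if (max(vapply(pages, max, numeric(1L))) > 255) "uint16" else "uint8"
  ImageStack(pages, pixelSizeNm = pixelSizeNm, dtype = dtype)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Integer-tagged stacks (`uint8`, `uint16`) are written at the matching bit
#' depth; `float32` stacks are written as IEEE-float pages.  Both round-trip
#' losslessly through [readImageStack()].
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(methods::is(stack, "ImageStack"))
  a <- stack@data
  n <- dim(a)[3L]
  if (stack@dtype == "float32") {
    writeFloatTiff(a, path)
  } else {
    full <- if (stack@dtype == "uint8") 255 else 65535
    if (min(a) < 0 || max(a) > full) {
      stop(sprintf("data exceed the %s range; retag the stack as float32",
                   stack@dtype))
    }
    pages <- lapply(seq_len(n), function(i) a[, , i] / full)
    ok <- tryCatch({
      tiff::writeTIFF(pages, path,
                      bits.per.sample = if (stack@dtype == "uint8") 8L else 16L)
      TRUE
    }, error = function(e) stop("cannot write TIFF to ", path, ": ",
                                conditionMessage(e)))
  }
  invisible(path)
}

#' Sum-bin consecutive frames of a stack
#'
#' Groups of `groupSize` consecutive frames are summed pixel-wise, emulating
#' a grouped sum z-projection.  Accumulation is done at full floating-point
#' precision (32-bit dynamic range or better) regardless of the input
#' storage type; the incomplete trailing group, if any, is dropped.  Used to
#' raise the apparent emitter density of SMLM acquisitions, e.g. 59,900 raw
#' frames become 14,975 frames at `groupSize = 4` and 5990 at 10.
#'
#' @param stack an [ImageStack-class].
#' @param groupSize number of consecutive frames per output frame (>= 1).
#' @return an [ImageStack-class] with `floor(n / groupSize)` frames, tagged
#'   `float32`.
#' @examples
#' s <- ImageStack(array(1, c(4, 4, 10)))
#' nFrames(binFrames(s, 4))  # 2
#' @export
binFrames <- function(stack, groupSize) {
  stopifnot(methods::is(stack, "ImageStack"))
  if (length(groupSize) != 1L || groupSize < 1 || groupSize != round(groupSize)) {
    stop("groupSize must be a single integer >= 1")
  }
  g <- as.integer(groupSize)
  d <- dim(stack@data)
  nOut <- d[3L] %/% g
  if (nOut < 1L) stop("stack has fewer frames than one group")
  flat <- matrix(stack@data[, , seq_len(nOut * g)], nrow = d[1L] * d[2L])
  arr3 <- array(flat, dim = c(d[1L] * d[2L], g, nOut))
  out <- colSums(aperm(arr3, c(2L, 1L, 3L)))   # sum over the group axis
  ImageStack(array(out, dim = c(d[1L], d[2L], nOut)),
             pixelSizeNm = stack@pixelSizeNm, dtype = "float32")
}

#' Split every frame of a stack into non-overlapping tiles
#'
#' Tiles are emitted in row-major order (top-left tile first, then across,
#' then down), each keeping the full frame (depth) axis.  Tile dimensions
#' must divide the frame dimensions evenly; a 1024 x 1024 x 32 stack split
#' with 512 x 512 tiles yields 4 sub-stacks of 512 x 512 x 32.
#'
#' @param stack an [ImageStack-class].
#' @param tileHeight,tileWidth tile dimensions in pixels.
#' @return a list of [ImageStack-class] tiles, `(H/th) * (W/tw)` per stack.
#' @export
splitTiles <- function(stack, tileHeight, tileWidth) {
  stopifnot(methods::is(stack, "ImageStack"))
  d <- dim(stack@data)
  if (d[1L] %% tileHeight != 0L || d[2L] %% tileWidth != 0L) {
    stop(sprintf("tile size %dx%d does not divide frame size %dx%d",
                 tileHeight, tileWidth, d[1L], d[2L]))
  }
  nr <- d[1L] %/% tileHeight
  nc <- d[2L] %/% tileWidth
  out <- vector("list", nr * nc)
  k <- 1L
  for (tr in seq_len(nr)) {
    for (tc in seq_len(nc)) {
      rows <- ((tr - 1L) * tileHeight + 1L):(tr * tileHeight)
      cols <- ((tc - 1L) * tileWidth + 1L):(tc * tileWidth)
      out[[k]] <- ImageStack(stack@data[rows, cols, , drop = FALSE],
                             pixelSizeNm = stack@pixelSizeNm,
                             dtype = stack@dtype)
      k <- k + 1L
    }
  }
  out
}

#' PairedDataset: matched source/target image stacks
#'
#' @slot pairs list of `list(name, source, target)` entries with matching
#'   spatial shapes.
#' @exportClass PairedDataset
setClass("PairedDataset", slots = c(pairs = "list"))

setMethod("show", "PairedDataset", function(object) {
  cat(sprintf("PairedDataset: %d pair(s)\n", length(object@pairs)))
})

#' @describeIn PairedDataset number of pairs
#' @param x a `PairedDataset`
#' @export
setMethod("length", "PairedDataset", function(x) length(x@pairs))

#' Pair source and target image folders
#'
#' Supervised restoration/translation training needs every source image to
#' have exactly one target of identical shape.  Files are paired by
#' identical filename by default; files lacking a partner are reported with
#' a warning and excluded.  `byOrder = TRUE` pairs the sorted file lists
#' positionally instead (fragile: renaming a single file silently shifts
#' every later pair, so it is off by default).
#'
#' @param sourceDir,targetDir directories of TIFF files.
#' @param byOrder pair by sorted position instead of by filename.
#' @return a [PairedDataset-class].
#' @export
pairDatasets <- function(sourceDir, targetDir, byOrder = FALSE) {
  listTiffs <- function(d) {
    f <- list.files(d, pattern = "\\.tiff?$", ignore.case = TRUE)
    if (!length(f)) stop("no TIFF files found in ", d)
    sort(f)
  }
  src <- listTiffs(sourceDir)
  tgt <- listTiffs(targetDir)
  if (byOrder) {
    n <- min(length(src), length(tgt))
    if (length(src) != length(tgt)) {
      warning(sprintf("folder sizes differ (%d vs %d); pairing first %d",
                      length(src), length(tgt), n))
    }
    names <- src[seq_len(n)]
    matched <- data.frame(name = names, src = src[seq_len(n)],
                          tgt = tgt[seq_len(n)])
  } else {
    common <- intersect(src, tgt)
    for (f in setdiff(src, tgt)) warning("source file without target: ", f)
    for (f in setdiff(tgt, src)) warning("target file without source: ", f)
    matched <- data.frame(name = common, src = common, tgt = common)
  }
  if (!nrow(matched)) stop("no matched source/target pairs")
  pairs <- lapply(seq_len(nrow(matched)), function(i) {
    s <- readImageStack(file.path(sourceDir, matched$src[i]))
    t <- readImageStack(file.path(targetDir, matched$tgt[i]))
    if (!identical(dim(s)[1:2], dim(t)[1:2])) {
      stop(sprintf("shape mismatch in pair '%s': %s vs %s", matched$name[i],
                   paste(dim(s)[1:2], collapse = "x"),
                   paste(dim(t)[1:2], collapse = "x")))
    }
    list(name = matched$name[i], source = s, target = t)
  })
  methods::new("PairedDataset", pairs = pairs)
}

# column-name dialects accepted on read (ThunderSTORM and bare spellings)
.locDialect <- list(
  frame   = c("frame"),
  x       = c("x [nm]", "x"),
  y       = c("y [nm]", "y"),
  photons = c("intensity [photon]", "intensity", "photons"),
  sigma   = c("sigma [nm]", "sigma")
)

#' Read a ThunderSTORM-style localisation CSV
#'
#' Accepts both the bracketed ThunderSTORM spellings (`"x [nm]"`,
#' `"intensity [photon]"`) and bare column names (`"x"`, `"photons"`).
#' Coordinates are in nm.  Columns other than frame/x/y/photons/sigma are
#' preserved verbatim.
#'
#' @param path CSV file path.
#' @return a [LocalisationTable-class].
#' @seealso [writeLocalisations()]
#' @export
readLocalisations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  out <- list()
  used <- character()
  for (col in names(.locDialect)) {
    hit <- intersect(.locDialect[[col]], names(df))
    if (length(hit)) {
      out[[col]] <- as.numeric(df[[hit[1L]]])
      used <- c(used, hit[1L])
    } else if (col %in% c("frame", "x", "y")) {
      stop(sprintf(
        "missing mandatory column '%s' (accepted spellings: %s) in %s",
        col, paste(.locDialect[[col]], collapse = ", "), path))
    }
  }
  n <- length(out$frame)
  core <- data.frame(frame = out$frame, x = out$x, y = out$y,
                     photons = if (is.null(out$photons)) rep(NA_real_, n) else out$photons,
                     sigma = if (is.null(out$sigma)) rep(NA_real_, n) else out$sigma)
  if (n == 0L) {
    core <- core[0L, , drop = FALSE]
  }
  extra <- df[, setdiff(names(df), used), drop = FALSE]
  LocalisationTable(cbind(core, extra))
}

#' Write a localisation table as a ThunderSTORM-style CSV
#'
#' Canonical spellings (`"frame"`, `"x [nm]"`, `"y [nm]"`,
#' `"intensity [photon]"`, `"sigma [nm]"`) are written; extra columns are
#' appended verbatim.  The written file re-reads to the same values to
#' better than 1e-3 nm.
#'
#' @param table a [LocalisationTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLocalisations <- function(table, path) {
  stopifnot(methods::is(table, "LocalisationTable"))
  df <- table@records
  out <- data.frame(check.names = FALSE,
    "frame" = df$frame, "x [nm]" = df$x, "y [nm]" = df$y,
    "intensity [photon]" = df$photons, "sigma [nm]" = df$sigma)
  extra <- setdiff(names(df), c("frame", "x", "y", "photons", "sigma"))
  for (e in extra) out[[e]] <- df[[e]]
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
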