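# Minimal multi-page float32 TIFF writer.
#
# The CRAN 'tiff' package reads IEEE-float TIFFs but quantises on write, so
# lossless 32-bit float output (the storage contract for QC maps and binned
# stacks) is emitted here directly: little-endian, one strip per page,
# uncompressed, SampleFormat = IEEEFP.  Files are readable by tiff::readTIFF,
# Fiji and tifffile.

writeFloatTiff <- function(frames, path) {
  stopifnot(length(dim(frames)) == 3L)
  h <- dim(frames)[1L]; w <- dim(frames)[2L]; n <- dim(frames)[3L]
  stripBytes <- h * w * 4L
  entries <- 10L
  ifdBytes <- 2L + entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")

  # page i layout: [pixel strip][IFD]
  dataOff <- function(i) 8L + (i - 1L) * (stripBytes + ifdBytes)
  ifdOff <- function(i) dataOff(i) + stripBytes

  # header: byte order II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  wle(42L, 2L)
  wle(ifdOff(1L), 4L)

  entry <- function(tag, type, count, value) {
    wle(tag, 2L); wle(type, 2L); wle(count, 4L); wle(value, 4L)
  }

  for (i in seq_len(n)) {
    # TIFF strips are row-major
    writeBin(as.vector(t(frames[, , i])), con, size = 4L, endian = "little")
    wle(entries, 2L)
    entry(256L, 4L, 1L, w)               # ImageWidth
    entry(257L, 4L, 1L, h)               # ImageLength
    entry(258L, 3L, 1L, 32L)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)              # Compression: none
    entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
    entry(273L, 4L, 1L, dataOff(i))      # StripOffsets
    entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
    entry(278L, 4L, 1L, h)               # RowsPerStrip
    entry(279L, 4L, 1L, stripBytes)      # StripByteCounts
    entry(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
    wle(if (i < n) ifdOff(i + 1L) else 0L, 4L)  # next IFD
  }
  invisible(path)
}
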