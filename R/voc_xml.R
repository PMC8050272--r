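# PASCAL VOC XML annotation I/O (the format emitted by common browser
# annotation tools for object-detection training sets).  VOC coordinates
# are 1-based inclusive; they are converted to the package's 0-based
# half-open convention on read and back on write, so round trips are exact.

#' Read a PASCAL VOC XML annotation file
#'
#' @param path XML file path.
#' @return a [DetectionSet-class]; `<confidence>`/`<score>` elements, when
#'   present, populate the confidence column (otherwise `NA`, i.e. ground
#'   truth).
#' @export
readVOC <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  if (is.na(fname) || !nzchar(fname)) {
    fname <- tools::file_path_sans_ext(basename(path))
  }
  objs <- xml2::xml_find_all(doc, "./object")
  getNum <- function(node, xp) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    if (is.na(v) || !nzchar(v)) NA_real_ else as.numeric(v)
  }
  rows <- lapply(objs, function(o) {
    conf <- getNum(o, "./confidence")
    if (is.na(conf)) conf <- getNum(o, "./score")
    data.frame(class = xml2::xml_text(xml2::xml_find_first(o, "./name")),
               # 1-based inclusive -> 0-based half-open
               xmin = getNum(o, "./bndbox/xmin") - 1,
               ymin = getNum(o, "./bndbox/ymin") - 1,
               xmax = getNum(o, "./bndbox/xmax"),
               ymax = getNum(o, "./bndbox/ymax"),
               confidence = conf)
  })
  boxes <- if (length(rows)) do.call(rbind, rows)
           else data.frame(class = character(), xmin = numeric(),
                           ymin = numeric(), xmax = numeric(),
                           ymax = numeric(), confidence = numeric())
  DetectionSet(fname, boxes)
}

#' Write a DetectionSet as a PASCAL VOC XML file
#'
#' @param det a [DetectionSet-class].
#' @param path output XML path.
#' @param imageSize optional `c(height, width)` recorded in `<size>`.
#' @return `path`, invisibly.
#' @export
writeVOC <- function(det, path, imageSize = NULL) {
  stopifnot(methods::is(det, "DetectionSet"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", det@imageName)
  if (!is.null(imageSize)) {
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(imageSize[2L]))
    xml2::xml_add_child(sz, "height", as.character(imageSize[1L]))
    xml2::xml_add_child(sz, "depth", "1")
  }
  b <- det@boxes
  for (i in seq_len(nrow(b))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", b$class[i])
    if (!is.na(b$confidence[i])) {
      xml2::xml_add_child(o, "confidence", as.character(b$confidence[i]))
    }
    bb <- xml2::xml_add_child(o, "bndbox")
    # 0-based half-open -> 1-based inclusive
    xml2::xml_add_child(bb, "xmin", as.character(b$xmin[i] + 1))
    xml2::xml_add_child(bb, "ymin", as.character(b$ymin[i] + 1))
    xml2::xml_add_child(bb, "xmax", as.character(b$xmax[i]))
    xml2::xml_add_child(bb, "ymax", as.character(b$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
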