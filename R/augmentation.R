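# Deterministic D4 augmentation: the eight symmetries of the square applied
# to images, paired datasets and bounding boxes.  Rotations are expressed in
# matrix coordinates (rows = y increasing downward); "rot90" denotes the
# rotation taking the top row to the left column.

.d4Names <- c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v",
              "transpose", "anti_transpose")

#' Names of the eight D4 transforms
#'
#' `identity`, the three quarter-turn rotations, the horizontal and
#' vertical mirrors and the two diagonal reflections — the dihedral group
#' of the square.  [d4Inverse()] returns each element's inverse within the
#' set.
#'
#' @return character vector of length 8 in the package's deterministic
#'   order.
#' @export
d4Transforms <- function() .d4Names

#' @rdname d4Transforms
#' @param t a transform name.
#' @export
d4Inverse <- function(t) {
  checkChoice(t, .d4Names, "transform")
  switch(t, rot90 = "rot270", rot270 = "rot90", t)
}

#' Apply a D4 transform to a matrix
#'
#' @param m 2D matrix.
#' @param t transform name, see [d4Transforms()].
#' @return the transformed matrix (dimensions swap for `rot90`, `rot270`,
#'   `transpose`, `anti_transpose`).
#' @export
applyD4 <- function(m, t) {
  checkChoice(t, .d4Names, "transform")
  h <- nrow(m); w <- ncol(m)
  switch(t,
    identity = m,
    rot90 = t(m)[w:1, , drop = FALSE],
    rot180 = m[h:1, w:1, drop = FALSE],
    rot270 = t(m)[, h:1, drop = FALSE],
    flip_h = m[, w:1, drop = FALSE],
    flip_v = m[h:1, , drop = FALSE],
    transpose = t(m),
    anti_transpose = t(m)[w:1, h:1, drop = FALSE])
}

# continuous coordinate map of transform t on an image of width w, height h
# (x in [0, w], y in [0, h], origin at the top-left corner); returns the
# mapped (x, y) and the output image width/height
d4MapPoint <- function(x, y, w, h, t) {
  switch(t,
    identity       = list(x = x, y = y, w = w, h = h),
    rot90          = list(x = y, y = w - x, w = h, h = w),
    rot180         = list(x = w - x, y = h - y, w = w, h = h),
    rot270         = list(x = h - y, y = x, w = h, h = w),
    flip_h         = list(x = w - x, y = y, w = w, h = h),
    flip_v         = list(x = x, y = h - y, w = w, h = h),
    transpose      = list(x = y, y = x, w = h, h = w),
    anti_transpose = list(x = h - y, y = w - x, w = h, h = w))
}

#' D4-augment a source/target image pair
#'
#' Applies each of the eight square symmetries identically to both members,
#' multiplying the dataset by exactly 8 (the identity is included).  The
#' `"rot"` subgroup (4 rotations) and `"flip"` subset (identity + two
#' mirrors + their composition, i.e. rot180) are available for staged
#' augmentation protocols.
#'
#' @param source,target 2D matrices of identical shape.
#' @param mode `"d4"` (8 transforms), `"rot"` (4) or `"flip"` (4).
#' @return named list (one entry per transform) of
#'   `list(transform, source, target)`.
#' @export
d4AugmentPair <- function(source, target, mode = c("d4", "rot", "flip")) {
  mode <- match.arg(mode)
  stopIfShapeMismatch(source, target)
  ts <- switch(mode,
    d4 = .d4Names,
    rot = c("identity", "rot90", "rot180", "rot270"),
    flip = c("identity", "flip_h", "flip_v", "rot180"))
  out <- lapply(ts, function(t) list(transform = t,
                                     source = applyD4(source, t),
                                     target = applyD4(target, t)))
  names(out) <- ts
  out
}

#' Transform bounding boxes along with their image
#'
#' Maps each box's corners through the exact coordinate transform of `t` on
#' the half-open pixel grid and re-normalises so `xmin < xmax`,
#' `ymin < ymax`; class and confidence are preserved.  The transformed box
#' footprint coincides exactly with the transformed rasterised box.
#'
#' @param imageShape `c(height, width)` of the image the boxes live in.
#' @param det a [DetectionSet-class] with boxes inside the image bounds.
#' @param t transform name, see [d4Transforms()].
#' @return list with `det` (transformed [DetectionSet-class]) and `shape`
#'   (the output image `c(height, width)`).
#' @export
transformBoxes <- function(imageShape, det, t) {
  checkChoice(t, .d4Names, "transform")
  stopifnot(methods::is(det, "DetectionSet"))
  h <- imageShape[1L]; w <- imageShape[2L]
  b <- det@boxes
  if (nrow(b) && (any(b$xmin < 0) || any(b$ymin < 0) || any(b$xmax > w) ||
                  any(b$ymax > h))) {
    stop("box outside image bounds")
  }
  if (nrow(b)) {
    p1 <- d4MapPoint(b$xmin, b$ymin, w, h, t)
    p2 <- d4MapPoint(b$xmax, b$ymax, w, h, t)
    b2 <- data.frame(class = b$class,
                     xmin = pmin(p1$x, p2$x), ymin = pmin(p1$y, p2$y),
                     xmax = pmax(p1$x, p2$x), ymax = pmax(p1$y, p2$y),
                     confidence = b$confidence)
  } else {
    b2 <- b
  }
  mp <- d4MapPoint(0, 0, w, h, t)
  list(det = DetectionSet(paste0(det@imageName, "_", t), b2),
       shape = c(mp$h, mp$w))
}
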