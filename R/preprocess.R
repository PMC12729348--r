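#' Canvas geometry: center-crop then symmetric zero-pad
#'
#' The acquisition geometry crops frames to `crop_height` x `crop_width`
#' and pads them to `pad_height` x `pad_width` for network input (the
#' full-scale reference is 1024 x 690 cropped, padded to 1024 x 1024; the
#' desk-scale default divides everything by 8, i.e. 128 x 87 padded to
#' 128 x 128). Padding is centered, with the extra pixel going to the
#' bottom/right on odd remainders; the recorded offsets make mask/image
#' coordinates invertible.
#'
#' @param crop_height,crop_width crop size, pixels.
#' @param pad_height,pad_width padded size, pixels (>= crop size).
#' @param pad_value intensity used for padding (masks are padded with 0).
#' @return an object of class `canvas_spec` with recorded `pad_offsets`
#'   (top, left).
#' @export
canvas_spec <- function(crop_height = 128L, crop_width = 87L,
                        pad_height = 128L, pad_width = 128L, pad_value = 0) {
  stopifnot(pad_height >= crop_height, pad_width >= crop_width)
  structure(list(crop_height = as.integer(crop_height),
                 crop_width = as.integer(crop_width),
                 pad_height = as.integer(pad_height),
                 pad_width = as.integer(pad_width),
                 pad_value = pad_value,
                 pad_offsets = c(top = (pad_height - crop_height) %/% 2L,
                                 left = (pad_width - crop_width) %/% 2L)),
            class = "canvas_spec")
}

#' Fill a boundary tracing into a binary mask
#'
#' Nonzero-winding polygon fill over pixel centers (see [polygon_fill()]).
#'
#' @param tracing n x 2 matrix of (x, y) vertices, 0-based.
#' @param height,width raster size.
#' @return 0/1 integer matrix.
#' @export
fill_tracing <- function(tracing, height, width) {
  tracing <- unclass(tracing)
  if (!is.matrix(tracing) || nrow(tracing) < 3)
    stop("a tracing needs at least 3 vertices")
  if (any(tracing[, 1] < 0) || any(tracing[, 1] > width - 1) ||
      any(tracing[, 2] < 0) || any(tracing[, 2] > height - 1))
    stop("tracing vertex outside image bounds")
  polygon_fill(tracing, height, width)
}

#' Center-crop then pad an image to the canvas geometry
#'
#' @param image numeric matrix (an intensity image or a mask).
#' @param canvas a [canvas_spec].
#' @param is_mask pad with 0 (background) regardless of `pad_value`.
#' @return matrix of size pad_height x pad_width.
#' @export
crop_then_pad <- function(image, canvas, is_mask = FALSE) {
  stopifnot(inherits(canvas, "canvas_spec"))
  h <- nrow(image); w <- ncol(image)
  ch <- canvas$crop_height; cw <- canvas$crop_width
  if (h < ch || w < cw)
    stop("source image (", h, "x", w, ") smaller than crop size")
  top <- (h - ch) %/% 2L; left <- (w - cw) %/% 2L
  cropped <- image[top + seq_len(ch), left + seq_len(cw), drop = FALSE]
  pv <- if (is_mask) 0 else canvas$pad_value
  out <- matrix(pv, canvas$pad_height, canvas$pad_width)
  off <- canvas$pad_offsets
  out[off["top"] + seq_len(ch), off["left"] + seq_len(cw)] <- cropped
  if (is_mask) storage.mode(out) <- "integer"
  out
}

#' Undo the padding using the recorded offsets
#'
#' @param image padded matrix.
#' @param canvas the [canvas_spec] used to pad it.
#' @return the cropped interior, bit-exact.
#' @export
unpad <- function(image, canvas) {
  off <- canvas$pad_offsets
  image[off["top"] + seq_len(canvas$crop_height),
        off["left"] + seq_len(canvas$crop_width), drop = FALSE]
}

#' Binarize a mask raster
#'
#' Foreground iff value > 127 on the 0-255 scale. Rasters that are already
#' 0/1 are returned unchanged, which makes the operation idempotent.
#'
#' @param raster numeric matrix with values in \[0, 255\] (or already 0/1).
#' @return 0/1 integer matrix.
#' @export
binarize <- function(raster) {
  if (any(raster < 0) || any(raster > 255)) stop("raster values outside [0, 255]")
  if (all(raster %in% c(0, 1))) {
    out <- raster
  } else {
    out <- (raster > 127) * 1
  }
  storage.mode(out) <- "integer"
  matrix(out, nrow(raster), ncol(raster))
}

#' Apply canvas geometry to a list of pairs
#'
#' @param pairs phantom pairs.
#' @param canvas a [canvas_spec].
#' @return the pairs with image, mask (and manual_mask when present) cropped
#'   and padded.
#' @export
preprocess_pairs <- function(pairs, canvas) {
  lapply(pairs, function(p) {
    p$image <- crop_then_pad(p$image, canvas)
    p$mask <- crop_then_pad(p$mask, canvas, is_mask = TRUE)
    if (!is.null(p$manual_mask))
      p$manual_mask <- crop_then_pad(p$manual_mask, canvas, is_mask = TRUE)
    p
  })
}
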