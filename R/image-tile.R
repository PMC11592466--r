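#' Image tiles
#'
#' A tile is the unit of analysis: a small grayscale patch cut from a
#' whole-slide image (or generated synthetically), carried around as an
#' integer matrix of 8-bit intensities together with an identifier and an
#' optional binary outcome label (1 = relapse/metastasis, 0 = none).
#'
#' @param pixels Integer (or numeric, silently rounded) matrix with values in
#'   `[0, 255]` and both dimensions at least 2. A 3-d array is treated as an
#'   RGB image and converted to grayscale by the luminance formula.
#' @param tile_id Character identifier.
#' @param label Binary outcome label (`0`, `1`, or `NA` for unlabeled tiles).
#' @return An `image_tile`: a list with elements `pixels`, `tile_id`, `label`.
#' @examples
#' t <- image_tile(matrix(0:255, 16, 16), "t1", label = 0)
#' dim(t$pixels)
#' @export
image_tile <- function(pixels, tile_id = NA_character_, label = NA_integer_) {
  if (is.array(pixels) && length(dim(pixels)) == 3) {
    pixels <- rgb_to_gray(pixels)
  }
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    stop("tile must be at least 2x2", call. = FALSE)
  }
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(px) <- "integer"
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("`label` must be 0, 1 or NA", call. = FALSE)
  }
  structure(
    list(pixels = px, tile_id = as.character(tile_id),
         label = as.integer(label)),
    class = "image_tile"
  )
}

#' @export
print.image_tile <- function(x, ...) {
  cat(sprintf("<image_tile %s: %dx%d, label %s>\n",
              x$tile_id, nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' @rdname image_tile
#' @param x Object to test.
#' @export
is_image_tile <- function(x) inherits(x, "image_tile")

#' Convert an RGB array to 8-bit grayscale
#'
#' Uses the Rec. 601 luminance weights 0.299 R + 0.587 G + 0.114 B, the
#' standard grayscale conversion applied before all texture processing.
#'
#' @param rgb Numeric array `height x width x 3`, values in `[0, 255]` or
#'   `[0, 1]` (the latter is rescaled).
#' @return Integer matrix in `[0, 255]`.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  if (max(rgb) <= 1) rgb <- rgb * 255
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(as.integer(pmin(pmax(round(g), 0), 255)), nrow(g), ncol(g))
}

#' Read and write tiles as PNG
#'
#' @param tile An `image_tile`.
#' @param path File path.
#' @param tile_id,label Metadata attached to the tile read back.
#' @return `write_tile_png()` returns `path` invisibly; `read_tile_png()`
#'   returns an `image_tile` (RGB PNGs are converted to grayscale).
#' @export
write_tile_png <- function(tile, path) {
  png::writePNG(tile$pixels / 255, path)
  invisible(path)
}

#' @rdname write_tile_png
#' @export
read_tile_png <- function(path, tile_id = basename(path), label = NA_integer_) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- rgb_to_gray(img) / 255
  image_tile(round(img * 255), tile_id = tile_id, label = label)
}
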