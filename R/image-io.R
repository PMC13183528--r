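# 8-bit image representation and I/O.
#
# Images are plain numeric objects holding integer intensities 0..255:
# an H x W matrix (grayscale) or an H x W x 3 array (RGB). Binary masks are
# logical H x W matrices. PNG is the supported on-disk format.

# clamp to [0, 1] (keeps dim attributes)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# round-half-up quantization to 0..255 (keeps dim attributes)
quant8 <- function(x) {
  y <- floor(x + 0.5)
  y[y < 0] <- 0
  y[y > 255] <- 255
  y
}

assert_image8 <- function(img, arg = "img") {
  if (!(is.matrix(img) || (is.array(img) && length(dim(img)) == 3L &&
                           dim(img)[3L] %in% c(1L, 3L)))) {
    stop(sprintf("`%s` must be an H x W matrix or an H x W x 3 array", arg))
  }
  if (length(img) == 0L) stop(sprintf("`%s` is empty", arg))
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255)) {
    stop(sprintf("`%s` must contain finite intensities in [0, 255]", arg))
  }
  invisible(img)
}

n_channels <- function(img) if (is.matrix(img)) 1L else dim(img)[3L]

get_channel <- function(img, k) {
  if (is.matrix(img)) return(img)
  matrix(img[, , k], dim(img)[1L], dim(img)[2L])
}

set_channel <- function(img, k, v) {
  if (is.matrix(img)) v else { img[, , k] <- v; img }
}

#' Convert an RGB image to 8-bit luminance
#'
#' Uses the standard luminance weights `0.299 R + 0.587 G + 0.114 B`,
#' rounded half-up. Grayscale input is returned unchanged.
#'
#' @param img 8-bit image (matrix or H x W x 3 array).
#' @return H x W matrix of intensities 0..255.
#' @export
rgb_to_gray <- function(img) {
  assert_image8(img)
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (d[3L] == 1L) return(matrix(img[, , 1L], d[1L], d[2L]))
  matrix(quant8(0.299 * img[, , 1L] + 0.587 * img[, , 2L] +
                  0.114 * img[, , 3L]), d[1L], d[2L])
}

#' Read an 8-bit image from a PNG file
#'
#' @param path Path to a PNG file.
#' @return An H x W matrix (grayscale) or H x W x 3 array (RGB) of
#'   intensities 0..255. An alpha channel, if present, is dropped.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] == 2L) x <- x[, , 1L]              # gray + alpha
    else if (dim(x)[3L] == 4L) x <- x[, , 1:3]        # rgb + alpha
    else if (dim(x)[3L] == 1L) x <- x[, , 1L]
  }
  quant8(x * 255)
}

#' Write an 8-bit image (or binary mask) to a PNG file
#'
#' Masks (logical matrices) are written as single-channel 0/255 images.
#'
#' @param img 8-bit image, or a logical mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) {
    img <- matrix(as.numeric(img) * 255, nrow(img), ncol(img))
  }
  assert_image8(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' @param path Path to a 0/255 single-channel PNG.
#' @return Logical H x W matrix (`TRUE` = foreground, intensity >= 128).
#' @export
read_mask <- function(path) {
  rgb_to_gray(read_image(path)) >= 128
}
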