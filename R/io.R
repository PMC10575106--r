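# PNG input/output. Images are numeric arrays (H x W x 3) in [0, 1];
# masks are integer H x W matrices with values 0/1, stored as 0/255 PNG.

#' Write an RGB image or a binary mask as PNG
#'
#' @param x image array (H x W x 3, values in \[0, 1\]) or binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (is.matrix(x)) {
    assert_binary_mask(x, "x")
    png::writePNG(matrix(as.numeric(x), nrow(x), ncol(x)), path)
  } else {
    png::writePNG(clamp(x, 0, 1), path)
  }
  invisible(path)
}

#' Read a PNG image as an H x W x 3 array in \[0, 1\]
#' @param path PNG file path.
#' @return Numeric array H x W x 3.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Read a PNG mask as a binary 0/1 matrix
#' @param path PNG file path (any nonzero intensity is foreground).
#' @return Integer matrix of 0/1.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  m
}
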