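#' Read a PNG image
#'
#' Reads 8- or 16-bit PNG pixel data normalized to `[0, 1]`. A single-
#' channel file comes back as a grayscale matrix; a color file as an
#' `H x W x 3` RGB array (alpha, if present, is dropped) ready for
#' [rgb_to_gray()]. Gray+alpha files return the gray channel.
#'
#' @param path PNG file path.
#' @return Matrix (grayscale) or `H x W x 3` array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- tryCatch(png::readPNG(path), error = function(e) {
    abort(sprintf("cannot read %s as PNG: %s", path, conditionMessage(e)))
  })
  if (is.matrix(img)) return(img)
  nc <- dim(img)[3]
  if (nc == 2L) return(img[, , 1])        # gray + alpha
  img[, , 1:3]
}

#' Write a grayscale image as 8-bit PNG
#'
#' Quantizes unit-scale intensities to 8 bits with round-half-away-from-zero
#' (`level = floor(255 * v + 0.5)`), so a written image read back with
#' [read_image()] reproduces the quantized matrix bit-exactly.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_gray_image(img)
  q <- floor(255 * img + 0.5) / 255
  png::writePNG(q, target = path)
  invisible(path)
}
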