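#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF and maps it to the 0-255 floating
#' scale (a 16-bit maximum maps to 255). RGB inputs are converted to
#' luminance (0.299 R + 0.587 G + 0.114 B) with a warning; an alpha
#' channel, if present, is dropped.
#'
#' @param path File path; format chosen by extension (.png, .tif, .tiff).
#' @return Numeric matrix on the 0-255 scale.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format: .%s", ext),
                     call. = FALSE))
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    if (nch >= 3L) {
      warning(sprintf("RGB input %s converted to luminance", basename(path)),
              call. = FALSE)
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      img <- img[, , 1L] # gray + alpha
    }
  }
  img * 255
}

#' Write a grayscale image
#'
#' Clamps to \[0, 255\], rounds to 8-bit levels, and writes PNG or TIFF by
#' extension. `write_gray()` then [read_gray()] round-trips 8-bit data
#' exactly.
#'
#' @param img Numeric matrix on the 0-255 scale.
#' @param path Output path (.png, .tif, .tiff).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  check_gray(img)
  q <- quantize_u8(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(q, path),
         tif = ,
         tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
         stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  invisible(path)
}
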