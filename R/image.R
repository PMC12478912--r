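#' Validate a grayscale image matrix
#'
#' All operations in curvefuse work on plain numeric matrices holding real
#' intensities on the 0-255 scale. Intermediate subbands are signed and
#' unclamped; clamping to \[0, 255\] happens only at export
#' (see [write_gray()] and [quantize_u8()]).
#'
#' @param img Numeric matrix.
#' @param min_dim Minimum number of rows and columns required.
#' @param arg Name used in error messages.
#' @return The validated matrix, invisibly usable in pipelines.
#' @keywords internal
check_gray <- function(img, min_dim = 1L, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d", arg, min_dim, min_dim),
         call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(img)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("image dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(NULL)
}

#' Quantize an image to 8-bit levels
#'
#' Clamps to \[0, 255\] and rounds half to even (the IEC 60559 convention of
#' base R's `round()`). Histogram-based metrics (entropy, mutual
#' information) operate on this 256-level representation; gradient-based
#' metrics use the floating image directly.
#'
#' @param img Numeric matrix on the 0-255 scale.
#' @return Integer matrix with values in 0..255.
#' @export
#' @examples
#' quantize_u8(matrix(c(-5, 0.5, 127.5, 300), 2, 2))
quantize_u8 <- function(img) {
  check_gray(img)
  q <- round(pmin(pmax(img, 0), 255))
  storage.mode(q) <- "integer"
  q
}
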