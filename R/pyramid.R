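#' @title Multiscale decomposition and reconstruction
#' @description
#' The decomposition used by the fusion pipeline is a Gaussian residual
#' pyramid: at each level the current approximation L is split into a
#' detail subband H = L - G_sigma(L) (everything the heavy Gaussian blur
#' removes) and the next, half-resolution approximation
#' L' = downsample2(G_sigma(L)). A classical Laplacian pyramid backend with
#' a short binomial analysis filter is also provided; it stores exact
#' residuals and therefore reconstructs perfectly.
#' @name pyramid
NULL

# --- 1-D convolution and resampling operators -------------------------------
#
# All separable filtering is expressed as dense banded operator matrices so
# a 2-D pass is two matrix products: Op_rows %*% img %*% t(Op_cols). The
# boundary policy (symmetric half-sample reflection) is folded into the
# operator, and rows are renormalized so a constant signal is reproduced
# exactly in floating point.

# Map an out-of-range index onto 1..n by symmetric (half-sample) reflection:
# ... 2 1 | 1 2 ... n | n ... 1 | ...
reflect_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i >= n, 2L * n - 1L - i, i) + 1L
}

# n x n operator applying symmetric 1-D kernel k with reflective boundary.
conv_op <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  rows <- seq_len(n)
  for (t in seq_along(k)) {
    cols <- reflect_index(rows + (t - 1L - r), n)
    ij <- cbind(rows, cols)
    M[ij] <- M[ij] + k[t]
  }
  M / rowSums(M) # exact constant preservation
}

# Truncated, renormalized Gaussian tap vector (radius ceil(3*sigma)).
gauss_taps <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

sep_filter <- function(img, k) {
  # anchor shift: operator rows sum to 1, so filtering the deviation from a
  # reference value is algebraically identical but preserves constant
  # images bit-exactly in floating point
  anchor <- img[1L, 1L]
  anchor + conv_op(nrow(img), k) %*% (img - anchor) %*% t(conv_op(ncol(img), k))
}

#' Gaussian smoothing with a truncated, renormalized kernel
#'
#' Convolves with a separable 2-D Gaussian truncated at radius
#' `ceiling(3 * sigma)` and renormalized to unit mass; boundaries are
#' handled by symmetric reflection. With the pipeline default `sigma = 20`
#' the kernel spans 121 taps, so the boundary policy materially shapes the
#' subbands and is fixed here.
#'
#' @param img Numeric matrix (grayscale image).
#' @param sigma Positive standard deviation, in pixels.
#' @return Matrix of the same shape; values lie within the input range.
#' @export
#' @examples
#' gaussian_smooth(matrix(40, 8, 8), sigma = 20)[1, 1]
gaussian_smooth <- function(img, sigma) {
  check_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  sep_filter(img, gauss_taps(sigma))
}

#' Downsample by a factor of two
#'
#' Stride-2 sampling starting at the first pixel; odd dimensions follow the
#' ceiling convention, so an image of shape (h, w) becomes
#' (ceiling(h/2), ceiling(w/2)). In the pipeline this always follows the
#' heavy Gaussian smoothing, which is the anti-aliasing step.
#'
#' @param img Numeric matrix.
#' @return Matrix of shape `ceiling(dim(img) / 2)`.
#' @export
downsample2 <- function(img) {
  check_gray(img)
  img[seq.int(1L, nrow(img), 2L), seq.int(1L, ncol(img), 2L), drop = FALSE]
}

# Resampling operator: output index i samples input coordinate (i + 1) / 2
# (the adjoint of stride-2 decimation at index 1), linearly interpolated and
# clamped at the ends. Weights sum to one, so constants map to constants.
upsample_op <- function(n_out, n_in) {
  pos <- pmin(pmax((seq_len(n_out) + 1) / 2, 1), n_in)
  lo <- pmin(floor(pos), n_in - 1L)
  if (n_in == 1L) lo <- rep(1L, n_out)
  w <- pos - lo
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo)] <- W[cbind(seq_len(n_out), lo)] + (1 - w)
  hi <- pmin(lo + 1L, n_in)
  W[cbind(seq_len(n_out), hi)] <- W[cbind(seq_len(n_out), hi)] + w
  W
}

#' Upsample by a factor of two to an exact target shape
#'
#' Bilinear interpolation placing retained samples back on their original
#' (odd-index) grid positions, so `upsample2(downsample2(x), dim(x))` is
#' exact at retained pixels. The target shape must be `2 * dim - 1` or
#' `2 * dim` componentwise; recording per-level shapes in the pyramid
#' removes odd-size ambiguity.
#'
#' @param img Numeric matrix.
#' @param target_shape Integer vector `c(rows, cols)`.
#' @return Matrix with exactly `target_shape` dimensions.
#' @export
upsample2 <- function(img, target_shape) {
  check_gray(img)
  target_shape <- as.integer(target_shape)
  ok <- target_shape >= 2L * dim(img) - 1L & target_shape <= 2L * dim(img)
  if (length(target_shape) != 2L || !all(ok)) {
    stop(sprintf("target shape (%s) incompatible with %dx%d input",
                 paste(target_shape, collapse = ","), nrow(img), ncol(img)),
         call. = FALSE)
  }
  anchor <- img[1L, 1L] # see sep_filter(): constants map to constants exactly
  anchor + upsample_op(target_shape[1L], nrow(img)) %*% (img - anchor) %*%
    t(upsample_op(target_shape[2L], ncol(img)))
}

new_pyramid <- function(details, low, level_shapes, levels, sigma = NULL,
                        h = NULL, backend) {
  structure(
    list(details = details, low = low, level_shapes = level_shapes,
         levels = levels, sigma = sigma, h = h, backend = backend),
    class = "decomposition_pyramid"
  )
}

#' @export
print.decomposition_pyramid <- function(x, ...) {
  cat(sprintf("<decomposition_pyramid: %s, %d level(s)>\n", x$backend,
              x$levels))
  for (i in seq_len(x$levels)) {
    cat(sprintf("  H_%d: %dx%d\n", i, nrow(x$details[[i]]),
                ncol(x$details[[i]])))
  }
  cat(sprintf("  low: %dx%d\n", nrow(x$low), ncol(x$low)))
  invisible(x)
}

planned_shapes <- function(shape, levels) {
  shapes <- vector("list", levels + 1L)
  shapes[[1L]] <- as.integer(shape)
  for (i in seq_len(levels)) {
    shapes[[i + 1L]] <- as.integer(ceiling(shapes[[i]] / 2))
  }
  if (any(shapes[[levels + 1L]] < 2L)) {
    stop(sprintf("image %dx%d too small for %d level(s)",
                 shape[1L], shape[2L], levels), call. = FALSE)
  }
  shapes
}

#' Gaussian residual pyramid decomposition
#'
#' Recursively, from L_0 = `img`:
#' H_i = L_{i-1} - G_sigma(L_{i-1}) and L_i = downsample2(G_sigma(L_{i-1})).
#' The detail subbands isolate texture and edges; the terminal low image
#' carries the global intensity structure. Defaults follow the fusion
#' pipeline: three levels and a heavy blur, sigma = 20.
#'
#' @param img Numeric matrix.
#' @param levels Number of decomposition levels (>= 1).
#' @param sigma Gaussian standard deviation in pixels.
#' @return A `decomposition_pyramid` with fields `details` (list H_1..H_L),
#'   `low` (terminal L_L), `level_shapes` (shapes of L_0..L_L), `levels`,
#'   `sigma`, `backend`.
#' @seealso [reconstruct()], [lp_decompose()]
#' @export
decompose <- function(img, levels = 3L, sigma = 20) {
  check_gray(img)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  shapes <- planned_shapes(dim(img), levels)
  details <- vector("list", levels)
  L <- img
  for (i in seq_len(levels)) {
    S <- gaussian_smooth(L, sigma)
    details[[i]] <- L - S
    L <- downsample2(S)
  }
  new_pyramid(details, L, shapes, levels, sigma = sigma,
              backend = "gaussian_residual")
}

#' Coarse-to-fine reconstruction
#'
#' Applies R_L = `low`; R_{i-1} = upsample2(R_i) + H_i down to the full
#' image. The single-upsampling form this generalizes is shape-inconsistent
#' for more than one level, so the recursive reading is canonical here.
#' The Gaussian residual scheme is near-identity but not exact
#' (upsampling after decimation is not the identity); the Laplacian
#' backend's residuals make [lp_reconstruct()] exact.
#'
#' @param low Terminal low-frequency matrix, or a `decomposition_pyramid`
#'   (in which case the remaining arguments are taken from it).
#' @param details List of detail subbands H_1..H_L.
#' @param level_shapes List of shapes of L_0..L_L.
#' @return Full-size numeric matrix.
#' @export
reconstruct <- function(low, details = NULL, level_shapes = NULL) {
  if (inherits(low, "decomposition_pyramid")) {
    details <- low$details
    level_shapes <- low$level_shapes
    low <- low$low
  }
  levels <- length(details)
  if (length(level_shapes) != levels + 1L) {
    stop("`level_shapes` must list the shapes of L_0..L_L", call. = FALSE)
  }
  if (!identical(dim(low), as.integer(level_shapes[[levels + 1L]]))) {
    stop("`low` does not match the recorded terminal shape", call. = FALSE)
  }
  R <- low
  for (i in rev(seq_len(levels))) {
    if (!identical(dim(details[[i]]), as.integer(level_shapes[[i]]))) {
      stop(sprintf("detail subband %d does not match recorded shape", i),
           call. = FALSE)
    }
    R <- upsample2(R, level_shapes[[i]]) + details[[i]]
  }
  R
}

#' Default Laplacian-pyramid analysis filter
#'
#' The classical 5-tap binomial low-pass, \[1, 4, 6, 4, 1\] / 16.
#' @return Numeric vector of length 5.
#' @export
binomial5 <- function() c(1, 4, 6, 4, 1) / 16

#' Classical Laplacian pyramid decomposition
#'
#' L_{i+1} = downsample2(L_i * h); H_i = L_i - upsample2(L_{i+1}).
#' Because each H_i stores the exact residual against the interpolated
#' coarser level, [lp_reconstruct()] inverts the transform to floating-point
#' accuracy for arbitrary images.
#'
#' @param img Numeric matrix.
#' @param levels Number of levels (>= 1).
#' @param h Normalized 1-D low-pass analysis kernel (odd length).
#' @return A `decomposition_pyramid` with `backend = "laplacian_pyramid"`.
#' @export
lp_decompose <- function(img, levels = 3L, h = binomial5()) {
  check_gray(img)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  if (length(h) %% 2L != 1L || abs(sum(h) - 1) > 1e-8) {
    stop("`h` must be an odd-length normalized kernel", call. = FALSE)
  }
  shapes <- planned_shapes(dim(img), levels)
  details <- vector("list", levels)
  L <- img
  for (i in seq_len(levels)) {
    Lnext <- downsample2(sep_filter(L, h))
    details[[i]] <- L - upsample2(Lnext, dim(L))
    L <- Lnext
  }
  new_pyramid(details, L, shapes, levels, h = h, backend = "laplacian_pyramid")
}

#' Exact Laplacian pyramid reconstruction
#'
#' Inverse of [lp_decompose()]: L_i = upsample2(L_{i+1}) + H_i, applied
#' coarse to fine. Exact to floating-point tolerance by construction.
#'
#' @param pyr A `decomposition_pyramid`.
#' @param h Ignored (kept for interface symmetry with [lp_decompose()]; the
#'   residual form needs no synthesis filter).
#' @return Full-size numeric matrix.
#' @export
lp_reconstruct <- function(pyr, h = NULL) {
  stopifnot(inherits(pyr, "decomposition_pyramid"))
  reconstruct(pyr)
}
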