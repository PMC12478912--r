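#' @title Synthetic co-registered modality phantoms
#' @description
#' Deterministic generation of two-modality brain-slice phantoms so every
#' pipeline stage and metric is testable without clinical data. Image A is
#' MRI-like (T2-weighted character: smooth soft-tissue blobs, a bright
#' central fluid region, dark skull); image B is CT-like (hyperdense bright
#' skull ring, flat low-contrast interior). Shared geometry guarantees
#' pixelwise co-registration; seeded Gaussian noise emulates acquisition
#' noise.
#' @name synthetic
NULL

#' Specification of a synthetic phantom pair
#'
#' Identical specs produce bitwise-identical image pairs; the seed is
#' explicit and no global RNG state leaks (the generator runs under a
#' scoped seed). Geometry is expressed in fractions of `min(height, width)`
#' so specs scale.
#'
#' @param height,width Image dimensions in pixels (default 256).
#' @param seed Integer RNG seed.
#' @param noise_sd Additive Gaussian noise standard deviation, intensity
#'   units on the 0-255 scale (default 2).
#' @param ring_radii Inner/outer skull-ring radii as fractions of
#'   `min(height, width)` (default `c(0.40, 0.46)`).
#' @param ring_intensity CT skull brightness (default 230).
#' @param tissue_blobs List of soft-tissue blobs, each
#'   `list(center = c(y, x) fractions, sd = pixels-fraction, amplitude)`.
#' @param fluid_axes Semi-axes (y, x) of the bright fluid ellipse, as
#'   fractions of `min(height, width)` (default `c(0.16, 0.10)`).
#' @param fluid_intensity MRI fluid (CSF-like) brightness (default 200).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 256L, width = 256L, seed = 1L,
                         noise_sd = 2,
                         ring_radii = c(0.40, 0.46),
                         ring_intensity = 230,
                         tissue_blobs = list(
                           list(center = c(0.38, 0.40), sd = 0.10, amplitude = 45),
                           list(center = c(0.62, 0.58), sd = 0.13, amplitude = -35),
                           list(center = c(0.45, 0.66), sd = 0.08, amplitude = 30)
                         ),
                         fluid_axes = c(0.16, 0.10),
                         fluid_intensity = 200) {
  if (height < 8L || width < 8L) {
    stop("phantom dimensions must be at least 8x8", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(ring_radii) != 2L || any(ring_radii <= 0) ||
      ring_radii[1L] >= ring_radii[2L] || ring_radii[2L] >= 0.5) {
    stop("`ring_radii` must satisfy 0 < inner < outer < 0.5", call. = FALSE)
  }
  if (any(fluid_axes <= 0) || any(fluid_axes >= ring_radii[1L])) {
    stop("fluid ellipse must fit inside the skull ring", call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         seed = as.integer(seed), noise_sd = noise_sd,
         ring_radii = ring_radii, ring_intensity = ring_intensity,
         tissue_blobs = tissue_blobs, fluid_axes = fluid_axes,
         fluid_intensity = fluid_intensity),
    class = "phantom_spec"
  )
}

#' Generate a co-registered MRI-like / CT-like phantom pair
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `a` (MRI-like) and `b` (CT-like), numeric
#'   matrices clamped to \[0, 255\].
#' @export
#' @examples
#' pair <- make_phantom_pair(phantom_spec(seed = 7))
#' c(dim(pair$a), range(pair$b))
make_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  s <- min(h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt((y - cy)^2 + (x - cx)^2)
  r_in <- spec$ring_radii[1L] * s
  r_out <- spec$ring_radii[2L] * s

  inside <- r < r_in
  ring <- r >= r_in & r <= r_out
  outside <- r > r_out

  # MRI-like: smooth tissue contrast inside, bright fluid, dark skull
  a <- matrix(0, h, w)
  tissue <- matrix(90, h, w)
  for (blob in spec$tissue_blobs) {
    by <- blob$center[1L] * h; bx <- blob$center[2L] * w
    tissue <- tissue +
      blob$amplitude * exp(-((y - by)^2 + (x - bx)^2) / (2 * (blob$sd * s)^2))
  }
  a[inside] <- tissue[inside]
  ell <- ((y - cy) / (spec$fluid_axes[1L] * s))^2 +
    ((x - cx) / (spec$fluid_axes[2L] * s))^2 < 1
  a[ell & inside] <- spec$fluid_intensity
  a[ring] <- 20
  a[outside] <- 5

  # CT-like: hyperdense skull, flat interior
  b <- matrix(0, h, w)
  b[inside] <- 70
  b[ring] <- spec$ring_intensity
  b[outside] <- 5

  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed, {
      list(a = matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w),
           b = matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
    })
    a <- a + noise$a
    b <- b + noise$b
  }
  list(a = pmin(pmax(a, 0), 255), b = pmin(pmax(b, 0), 255))
}

#' Closed-form analytic test images
#'
#' Fixtures with known analytic structure, used by the closed-form metric
#' and curvature checks: a constant, a unit-slope ramp, the 2x2
#' checkerboard `[[0, 255], [255, 0]]`, a centered unit impulse, a distance
#' cone (value 0 at the center pixel), and a saddle rescaled into
#' \[0, 255\]. Odd-sized fixtures have an exact center pixel.
#'
#' @param size Side length for the square fixtures (odd ones use
#'   `size + !(size %% 2)`).
#' @return Named list of numeric matrices, all finite and within
#'   \[0, 255\].
#' @export
analytic_fixtures <- function(size = 64L) {
  size <- as.integer(size)
  odd <- size + (1L - size %% 2L)
  c0 <- (odd + 1L) %/% 2L
  y <- matrix(seq_len(odd), odd, odd)
  x <- matrix(seq_len(odd), odd, odd, byrow = TRUE)
  impulse <- matrix(0, odd, odd)
  impulse[c0, c0] <- 255
  cone <- sqrt((y - c0)^2 + (x - c0)^2)
  saddle_raw <- (y - c0) * (x - c0)
  saddle <- 127.5 + 127.5 * saddle_raw / max(abs(saddle_raw))
  list(
    constant = matrix(40, size, size),
    ramp = matrix(seq_len(size) - 1L, size, size, byrow = TRUE),
    checkerboard = matrix(c(0, 255, 255, 0), 2L, 2L),
    impulse = impulse,
    cone = cone,
    saddle = saddle
  )
}
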