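test_that("gaussian smoothing preserves constants, mass and linear ramps", {
  expect_equal(gaussian_smooth(matrix(40, 16, 16), sigma = 20),
               matrix(40, 16, 16))

  # normalized kernel: a unit impulse keeps unit mass
  imp <- matrix(0, 201, 201)
  imp[101, 101] <- 1
  expect_equal(sum(gaussian_smooth(imp, sigma = 2)), 1, tolerance = 1e-9)

  # symmetric kernel convolved with a linear function reproduces it away
  # from the boundary
  ramp <- matrix(rep(seq_len(64), each = 64), 64, 64)
  sm <- gaussian_smooth(ramp, sigma = 3)
  interior <- 11:54 # > 3 * sigma from either edge
  expect_lt(max(abs(sm[, interior] - ramp[, interior])), 1e-6)

  # output values stay within the input range
  img <- seeded_image(11, 48)
  sm <- gaussian_smooth(img, sigma = 5)
  expect_gte(min(sm), min(img))
  expect_lte(max(sm), max(img))

  expect_error(gaussian_smooth(img, sigma = 0), "positive")
  expect_error(gaussian_smooth(matrix(c(1, NA, 3, 4), 2, 2), 1),
               "non-finite")
})

test_that("gaussian smoothing matches direct dense 2-D convolution", {
  img <- seeded_image(5, 40)
  for (sigma in c(1.5, 4)) {
    expect_equal(gaussian_smooth(img, sigma),
                 oracle_conv2(img, oracle_gauss2d(sigma)),
                 tolerance = 1e-12)
  }
})

test_that("downsampling follows the ceiling convention", {
  expect_identical(dim(downsample2(matrix(0, 8, 8))), c(4L, 4L))
  expect_identical(dim(downsample2(matrix(0, 7, 7))), c(4L, 4L))
  expect_equal(downsample2(matrix(13, 10, 6)), matrix(13, 5, 3))
  # stride-2 sampling keeps the odd-index grid
  img <- seeded_image(2, 8)
  expect_identical(downsample2(img), img[c(1, 3, 5, 7), c(1, 3, 5, 7)])
})

test_that("upsampling hits the exact target shape and inverts decimation", {
  expect_equal(upsample2(matrix(10, 4, 4), c(8, 8)), matrix(10, 8, 8))
  expect_identical(dim(upsample2(seeded_image(3, 4), c(7, 7))), c(7L, 7L))
  expect_error(upsample2(matrix(0, 4, 4), c(10, 8)), "incompatible")

  # retained samples are reproduced exactly
  img <- seeded_image(4, 9)
  up <- upsample2(downsample2(img), dim(img))
  odd <- c(1, 3, 5, 7, 9)
  expect_equal(up[odd, odd], img[odd, odd], tolerance = 1e-12)

  # after heavy blur, decimation + interpolation is near-identity
  smooth <- gaussian_smooth(make_phantom_pair(phantom_spec(seed = 1))$a, 20)
  expect_lt(rel_rmse(upsample2(downsample2(smooth), dim(smooth)), smooth),
            0.02)
})

test_that("decomposition produces the documented shapes and residuals", {
  pyr <- decompose(seeded_image(6, 64), levels = 3, sigma = 20)
  expect_s3_class(pyr, "decomposition_pyramid")
  expect_identical(vapply(pyr$details, nrow, 0L), c(64L, 32L, 16L))
  expect_identical(dim(pyr$low), c(8L, 8L))
  expect_identical(pyr$level_shapes[[4]], c(8L, 8L))

  # constant image: all details vanish identically
  cpyr <- decompose(matrix(77, 32, 32))
  for (H in cpyr$details) expect_equal(max(abs(H)), 0)
  expect_equal(cpyr$low, matrix(77, 4, 4))

  expect_error(decompose(matrix(0, 4, 4), levels = 3), "too small")
})

test_that("decomposition equals an independent step-by-step computation", {
  img <- make_phantom_pair(phantom_spec(height = 64, width = 64, seed = 8))$a
  pyr <- decompose(img, levels = 3, sigma = 20)
  k2d <- oracle_gauss2d(20)
  L <- img
  for (i in 1:3) {
    S <- oracle_conv2(L, k2d)
    H <- L - S
    L <- S[seq(1, nrow(S), 2), seq(1, ncol(S), 2), drop = FALSE]
    expect_equal(pyr$details[[i]], H, tolerance = 1e-9)
  }
  expect_equal(pyr$low, L, tolerance = 1e-9)
})

test_that("decomposition is linear subband-wise", {
  x <- seeded_image(21, 32)
  y <- seeded_image(22, 32)
  px <- decompose(x, 2, 8)
  py <- decompose(y, 2, 8)
  pz <- decompose(2 * x - 0.5 * y, 2, 8)
  for (i in 1:2) {
    expect_equal(pz$details[[i]], 2 * px$details[[i]] - 0.5 * py$details[[i]],
                 tolerance = 1e-10)
  }
  expect_equal(pz$low, 2 * px$low - 0.5 * py$low, tolerance = 1e-10)
})

test_that("reconstruction is exact for constants and near-identity overall", {
  expect_equal(reconstruct(matrix(40, 4, 4),
                           list(matrix(0, 13, 13), matrix(0, 7, 7)),
                           list(c(13L, 13L), c(7L, 7L), c(4L, 4L))),
               matrix(40, 13, 13))
  cimg <- matrix(12.5, 32, 32)
  expect_equal(reconstruct(decompose(cimg)), cimg)

  smooth <- make_phantom_pair(phantom_spec(seed = 2, noise_sd = 0))$a
  expect_lt(rel_rmse(reconstruct(decompose(smooth, 3, 20)), smooth), 0.02)

  pyr <- decompose(matrix(0, 32, 32))
  pyr$details[[1]] <- matrix(0, 5, 5)
  expect_error(reconstruct(pyr), "shape")
})

test_that("Laplacian pyramid round-trips exactly", {
  for (seed in 1:5) {
    img <- seeded_image(seed, 32)
    pyr <- lp_decompose(img, levels = 3)
    expect_identical(vapply(pyr$details, nrow, 0L), c(32L, 16L, 8L))
    expect_lt(max(abs(lp_reconstruct(pyr) - img)), 1e-9)
  }

  cpyr <- lp_decompose(matrix(5, 16, 16), 2)
  for (H in cpyr$details) expect_equal(max(abs(H)), 0)

  # single-level impulse round trip
  imp <- matrix(0, 17, 17); imp[9, 9] <- 1
  expect_lt(max(abs(lp_reconstruct(lp_decompose(imp, 1)) - imp)), 1e-9)

  # all-zero pyramid reconstructs to zero
  z <- lp_decompose(matrix(0, 16, 16), 2)
  expect_equal(lp_reconstruct(z), matrix(0, 16, 16))

  expect_error(lp_decompose(seeded_image(1, 16), 2, h = c(0.5, 0.5)),
               "odd-length")
})
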