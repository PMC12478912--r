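test_that("intensity and contrast metrics match closed forms", {
  expect_equal(metric_api(matrix(40, 5, 5)), 40)
  checker <- analytic_fixtures()$checkerboard
  expect_equal(metric_api(checker), 127.5)

  expect_equal(metric_sd(matrix(7, 4, 4)), 0)
  expect_equal(metric_sd(checker), 127.5)
  # two-level image, p = 0.5 at {0, a} -> sd = a / 2
  two <- matrix(c(0, 180), 6, 6)
  expect_equal(metric_sd(two), 90)
  # offset invariance
  img <- seeded_image(1, 16)
  expect_equal(metric_sd(img + 30), metric_sd(img))
  expect_equal(metric_sf(img + 30), metric_sf(img))
})

test_that("average gradient matches analytic and smoothing behavior", {
  expect_equal(metric_ag(matrix(3, 8, 8)), 0)
  ramp <- matrix(rep(0:15, each = 16), 16, 16)
  expect_equal(metric_ag(ramp, divisor = "valid"), 1)
  expect_equal(metric_ag(ramp), 1 * 15 * 15 / 256)
  noisy <- seeded_image(2, 32)
  expect_lte(metric_ag(gaussian_smooth(noisy, 4)), metric_ag(noisy))
})

test_that("entropy matches closed forms and bounds", {
  expect_equal(metric_entropy(matrix(99, 9, 9)), 0)
  uniform <- matrix(0:255, 16, 16)
  expect_equal(metric_entropy(uniform), 8, tolerance = 1e-12)
  expect_equal(metric_entropy(matrix(c(10, 200), 8, 8)), 1)
  for (seed in 1:3) {
    h <- metric_entropy(seeded_image(seed, 24))
    expect_gte(h, 0); expect_lte(h, 8)
  }
})

test_that("mutual information: identity, symmetry, independence", {
  img <- seeded_image(3, 32)
  expect_equal(metric_mi(img, img), metric_entropy(img), tolerance = 1e-12)
  other <- seeded_image(4, 32)
  expect_equal(metric_mi(img, other), metric_mi(other, img),
               tolerance = 1e-12)

  # independent noise fields at the generator's noise level share almost
  # no information (finite-sample histogram bias stays under 0.05 bits)
  n1 <- withr::with_seed(5, matrix(100 + stats::rnorm(256^2, 0, 2), 256, 256))
  n2 <- withr::with_seed(6, matrix(100 + stats::rnorm(256^2, 0, 2), 256, 256))
  expect_lte(metric_mi(n1, n2), 0.05)
})

test_that("MI-derived scores: additivity, fusion symmetry variants", {
  f <- seeded_image(7, 16)
  a <- seeded_image(8, 16)
  b <- seeded_image(9, 16)
  expect_equal(metric_mif(f, a, b), metric_mi(f, a) + metric_mi(f, b))
  expect_equal(metric_mif(f, f, f), 2 * metric_entropy(f), tolerance = 1e-12)

  # identical sources split information perfectly evenly
  expect_equal(metric_fs1(f, a, a, variant = "printed"), 0)
  expect_equal(metric_fs1(f, a, a), 2)

  # wiring against the definitional formulas
  mia <- metric_mi(f, a); mib <- metric_mi(f, b)
  expect_equal(metric_fs1(f, a, b, variant = "printed"),
               (mia - mib) / (mia + mib))
  expect_equal(metric_fs1(f, a, b), 2 - abs(mia / (mia + mib) - 0.5))
  expect_gte(metric_fs1(f, a, b), 1.5)
  expect_lte(metric_fs1(f, a, b), 2)
})

test_that("correlation: identity, negation, affine invariance, degeneracy", {
  a <- seeded_image(10, 16)
  expect_equal(metric_corr(a, a, mode = "a"), 1)
  expect_equal(metric_corr(255 - a, a, mode = "a"), -1)
  expect_equal(metric_corr(2 * a + 5, a, mode = "a"), 1, tolerance = 1e-12)
  b <- seeded_image(11, 16)
  expect_equal(metric_corr(a, a, b),
               (1 + metric_corr(a, b, mode = "a")) / 2)
  expect_error(metric_corr(matrix(1, 16, 16), a, mode = "a"), "constant")
})

test_that("spatial frequency matches hand arithmetic", {
  expect_equal(metric_sf(matrix(5, 6, 6)), 0)
  expect_equal(metric_sf(analytic_fixtures()$checkerboard), 255)
})

test_that("QAB/F: perfect, null and negated fusion behave as expected", {
  pair <- make_phantom_pair(phantom_spec(height = 96, width = 96, seed = 12))
  expect_equal(metric_qabf(pair$a, pair$a, pair$a), 1, tolerance = 1e-6)
  expect_lt(metric_qabf(matrix(50, 96, 96), pair$a, pair$b), 1e-3)

  q <- metric_qabf(fuse_images(pair$a, pair$b), pair$a, pair$b)
  expect_gte(q, 0); expect_lte(q, 1)

  # invariant under simultaneous intensity negation of all three images
  f <- fuse_images(pair$a, pair$b)
  expect_equal(metric_qabf(255 - f, 255 - pair$a, 255 - pair$b),
               metric_qabf(f, pair$a, pair$b), tolerance = 1e-12)
})

test_that("metric report assembles the standard columns", {
  pair <- make_phantom_pair(phantom_spec(height = 96, width = 96, seed = 13))
  f <- fuse_images(pair$a, pair$b)
  rep <- fusion_metrics(f, pair$a, pair$b)
  expect_identical(names(rep),
                   c("API", "SD", "AG", "Entropy", "MIF", "FS1", "Corr",
                     "SF", "QABF"))
  expect_equal(rep$API, metric_api(f))
  expect_equal(rep$QABF, metric_qabf(f, pair$a, pair$b))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, csv)
  expect_equal(utils::read.csv(csv)$SF, rep$SF, tolerance = 1e-9)
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, js)
  expect_equal(jsonlite::read_json(js)[[1]]$Entropy, rep$Entropy,
               tolerance = 1e-9)
})
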