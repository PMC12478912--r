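# Independent straight-line reference implementations used as oracles.
# These deliberately avoid the package's operator-matrix machinery: dense
# 2-D kernels, explicit index reflection and plain double loops.

# Symmetric half-sample reflection of an index vector onto 1..n.
oracle_reflect <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i >= n, 2L * n - 1L - i, i) + 1L
}

# Direct dense 2-D convolution with a full (non-separable) kernel and
# reflective boundary.
oracle_conv2 <- function(img, k2d) {
  r <- (nrow(k2d) - 1L) %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  rows <- seq_len(nrow(img))
  cols <- seq_len(ncol(img))
  for (dy in -r:r) {
    ry <- oracle_reflect(rows + dy, nrow(img))
    for (dx in -r:r) {
      rx <- oracle_reflect(cols + dx, ncol(img))
      out <- out + k2d[dy + r + 1L, dx + r + 1L] * img[ry, rx]
    }
  }
  out
}

oracle_gauss2d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k2d <- outer(k, k)
  k2d / sum(k2d)
}

oracle_entropy <- function(img) {
  q <- as.vector(round(pmin(pmax(img, 0), 255)))
  h <- 0
  for (lev in 0:255) {
    p <- sum(q == lev) / length(q)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(f, a) {
  qf <- as.vector(round(pmin(pmax(f, 0), 255)))
  qa <- as.vector(round(pmin(pmax(a, 0), 255)))
  n <- length(qf)
  mi <- 0
  for (i in unique(qf)) {
    for (j in unique(qa)) {
      pij <- sum(qf == i & qa == j) / n
      if (pij > 0) {
        pi_ <- sum(qf == i) / n
        pj_ <- sum(qa == j) / n
        mi <- mi + pij * log2(pij / (pi_ * pj_))
      }
    }
  }
  mi
}

oracle_ag <- function(f, divisor = "mn") {
  m <- nrow(f); n <- ncol(f)
  total <- 0
  for (i in seq_len(m - 1L)) {
    for (j in seq_len(n - 1L)) {
      gx <- f[i, j + 1L] - f[i, j]
      gy <- f[i + 1L, j] - f[i, j]
      total <- total + sqrt(gx^2 + gy^2)
    }
  }
  total / if (divisor == "mn") m * n else (m - 1) * (n - 1)
}

oracle_sf <- function(f) {
  m <- nrow(f); n <- ncol(f)
  rf <- 0; cf <- 0
  for (i in seq_len(m - 1L)) for (j in seq_len(n)) {
    rf <- rf + (f[i + 1L, j] - f[i, j])^2
  }
  for (i in seq_len(m)) for (j in seq_len(n - 1L)) {
    cf <- cf + (f[i, j + 1L] - f[i, j])^2
  }
  sqrt(rf / (m * n) + cf / (m * n))
}

# Deterministic test images.
seeded_image <- function(seed, h = 32L, w = h, lo = 0, hi = 255) {
  withr::with_seed(seed, matrix(stats::runif(h * w, lo, hi), h, w))
}

seeded_int_image <- function(seed, h = 4L, w = 4L, levels = 0:255) {
  withr::with_seed(seed,
                   matrix(sample(levels, h * w, replace = TRUE), h, w))
}

rel_rmse <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))
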