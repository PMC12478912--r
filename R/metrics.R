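#' @title Fusion quality metric suite
#' @description
#' No-reference sharpness/contrast scores (API, SD, AG, SF, entropy) and
#' source-referenced information/similarity scores (MI-based fusion score,
#' fusion symmetry, correlation, QAB/F edge preservation). Histogram-based
#' metrics (entropy, mutual information and their derivatives) operate on
#' the 256-level quantization of [quantize_u8()]; gradient-based and
#' moment-based metrics use the floating image directly.
#' @name metrics
NULL

#' Average pixel intensity
#'
#' Arithmetic mean of all pixel intensities; higher values indicate a
#' brighter fused image.
#' @param f Numeric matrix.
#' @return Scalar.
#' @export
metric_api <- function(f) {
  check_gray(f)
  mean(f)
}

#' Standard deviation (contrast spread)
#'
#' Population standard deviation (divisor M*N); higher values indicate
#' stronger contrast.
#' @param f Numeric matrix.
#' @return Scalar >= 0.
#' @export
metric_sd <- function(f) {
  check_gray(f)
  sqrt(mean((f - mean(f))^2))
}

#' Average gradient (sharpness)
#'
#' Mean over pixels of sqrt(gx^2 + gy^2) with forward differences. The
#' printed index ranges run one past the array, so the sum covers valid
#' difference pairs only; `divisor = "mn"` keeps the full M*N denominator,
#' `divisor = "valid"` normalizes by the (M-1)(N-1) pairs actually summed
#' (under which a unit-slope ramp scores exactly 1).
#'
#' @param f Numeric matrix.
#' @param divisor `"mn"` (default) or `"valid"`.
#' @return Scalar >= 0.
#' @export
metric_ag <- function(f, divisor = c("mn", "valid")) {
  check_gray(f, min_dim = 2L)
  divisor <- match.arg(divisor)
  m <- nrow(f); n <- ncol(f)
  gy <- f[-1L, -n, drop = FALSE] - f[-m, -n, drop = FALSE]
  gx <- f[-m, -1L, drop = FALSE] - f[-m, -n, drop = FALSE]
  total <- sum(sqrt(gx^2 + gy^2))
  total / if (divisor == "mn") m * n else (m - 1) * (n - 1)
}

#' Shannon entropy of the 256-level histogram
#'
#' Entropy in bits of the uint8-quantized image; 0 * log 0 := 0, so the
#' value lies in \[0, 8\].
#' @param f Numeric matrix.
#' @return Scalar in \[0, 8\].
#' @export
metric_entropy <- function(f) {
  p <- tabulate(quantize_u8(f) + 1L, 256L) / length(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}

joint_histogram <- function(f, a) {
  check_same_shape(f, a)
  qf <- quantize_u8(f)
  qa <- quantize_u8(a)
  counts <- matrix(tabulate(qf * 256L + qa + 1L, 256L * 256L), 256L, 256L,
                   byrow = TRUE)
  list(counts = counts,
       marginal_f = rowSums(counts),
       marginal_a = colSums(counts))
}

#' Mutual information between two images (bits)
#'
#' Computed from the 256 x 256 joint histogram of the uint8-quantized
#' images; zero-probability cells contribute 0. MI(F, F) equals the
#' entropy of F.
#' @param f,a Numeric matrices of equal shape.
#' @return Scalar >= 0.
#' @export
metric_mi <- function(f, a) {
  jh <- joint_histogram(f, a)
  n <- length(f)
  pj <- jh$counts / n
  pf <- jh$marginal_f / n
  pa <- jh$marginal_a / n
  pos <- which(pj > 0, arr.ind = TRUE)
  p <- pj[pos]
  sum(p * log2(p / (pf[pos[, 1L]] * pa[pos[, 2L]])))
}

#' Mutual-information fusion score
#'
#' MIF = MI(F, A) + MI(F, B): total information the fused image retains
#' from the two sources.
#' @param f Fused image; `a`, `b` source images (equal shapes).
#' @param a,b Source images.
#' @return Scalar >= 0.
#' @export
metric_mif <- function(f, a, b) {
  metric_mi(f, a) + metric_mi(f, b)
}

#' Fusion symmetry
#'
#' How evenly the fused image draws information from the two sources.
#' The `"printed"` variant is (MI(F,A) - MI(F,B)) / (MI(F,A) + MI(F,B)),
#' bounded by \[-1, 1\] and 0 for perfectly balanced fusion. Published
#' comparison tables for this family of methods report values in
#' \[1.5, 2\], consistent instead with
#' 2 - |MI(F,A) / (MI(F,A) + MI(F,B)) - 0.5|, which is the
#' `"table_scale"` default (2 = perfectly balanced).
#'
#' @param f,a,b Fused and source images.
#' @param variant `"table_scale"` (default) or `"printed"`.
#' @return Scalar.
#' @export
metric_fs1 <- function(f, a, b, variant = c("table_scale", "printed")) {
  variant <- match.arg(variant)
  mia <- metric_mi(f, a)
  mib <- metric_mi(f, b)
  if (mia + mib == 0) stop("degenerate images: MI(F,A) + MI(F,B) = 0",
                           call. = FALSE)
  if (variant == "printed") {
    (mia - mib) / (mia + mib)
  } else {
    2 - abs(mia / (mia + mib) - 0.5)
  }
}

#' Correlation between fused image and sources
#'
#' Pearson correlation of pixel intensities. Comparison tables print one
#' column, so the default reports the mean of Corr(F, A) and Corr(F, B);
#' `mode = "a"` or `"b"` selects a single pairing. A constant image has no
#' defined correlation and raises an error.
#'
#' @param f,a Fused and first source image.
#' @param b Second source image (required for `mode` `"mean"` or `"b"`).
#' @param mode `"mean"` (default), `"a"`, or `"b"`.
#' @return Scalar in \[-1, 1\].
#' @export
metric_corr <- function(f, a, b = NULL, mode = c("mean", "a", "b")) {
  mode <- match.arg(mode)
  corr1 <- function(x, y) {
    check_same_shape(x, y)
    if (stats::sd(as.vector(x)) == 0 || stats::sd(as.vector(y)) == 0) {
      stop("correlation undefined for a constant image", call. = FALSE)
    }
    stats::cor(as.vector(x), as.vector(y))
  }
  switch(mode,
         a = corr1(f, a),
         b = corr1(f, b),
         mean = (corr1(f, a) + corr1(f, b)) / 2)
}

#' Spatial frequency
#'
#' SF = sqrt(RF^2 + CF^2), where RF and CF are root-mean squared first
#' differences along the two axes. Sums run over valid index pairs; the
#' printed M*N divisor is the default, with `divisor = "valid"` as the
#' alternative.
#'
#' @param f Numeric matrix.
#' @param divisor `"mn"` (default) or `"valid"`.
#' @return Scalar >= 0.
#' @export
metric_sf <- function(f, divisor = c("mn", "valid")) {
  check_gray(f, min_dim = 2L)
  divisor <- match.arg(divisor)
  m <- nrow(f); n <- ncol(f)
  dr <- f[-1L, , drop = FALSE] - f[-m, , drop = FALSE]   # along rows (i+1, j)
  dc <- f[, -1L, drop = FALSE] - f[, -n, drop = FALSE]   # along cols (i, j+1)
  if (divisor == "mn") {
    rf <- sqrt(sum(dr^2) / (m * n))
    cf <- sqrt(sum(dc^2) / (m * n))
  } else {
    rf <- sqrt(mean(dr^2))
    cf <- sqrt(mean(dc^2))
  }
  sqrt(rf^2 + cf^2)
}

# Sobel gradient pair (reflective boundary, consistent with the rest of the
# package). Returns d/dx (columns) and d/dy (rows).
sobel_grad <- function(u) {
  smooth <- c(1, 2, 1) / 4
  gx <- conv_op(nrow(u), smooth) %*% u %*% t(diff_op(ncol(u)))
  gy <- diff_op(nrow(u)) %*% u %*% t(conv_op(ncol(u), smooth))
  list(gx = gx, gy = gy)
}

# Central-difference operator; reflected ends reduce to half one-sided
# differences at the borders.
diff_op <- function(n) {
  D <- matrix(0, n, n)
  rows <- seq_len(n)
  for (t in c(-1L, 1L)) {
    cols <- reflect_index(rows + t, n)
    ij <- cbind(rows, cols)
    D[ij] <- D[ij] + 0.5 * t
  }
  D
}

#' QAB/F edge-information preservation score
#'
#' The standard Sobel-based edge-preservation measure: per pixel, gradient
#' strength g and orientation alpha (atan of the component ratio, so the
#' score is invariant to simultaneous intensity negation) are extracted
#' from each source and the fused image; relative strength
#' G = min(g_s, g_f) / max(g_s, g_f) and relative orientation
#' A = 1 - |alpha_s - alpha_f| / (pi/2) are squashed through sigmoids with
#' the literature constants (strength: gamma 0.9994, slope -15, offset 0.5;
#' orientation: gamma 0.9879, slope -22, offset 0.8), each normalized to
#' equal 1 at perfect preservation; per-source preservation Q = Qg * Qa is
#' averaged over both sources weighted by source edge strength (exponent
#' L = 1). The result lies in \[0, 1\]; identical images score 1, a
#' constant fused image scores ~0.
#'
#' @param f,a,b Fused and source images, equal shapes.
#' @return Scalar in \[0, 1\].
#' @export
metric_qabf <- function(f, a, b) {
  check_same_shape(f, a)
  check_same_shape(f, b)
  ga <- sobel_grad(a); gb <- sobel_grad(b); gf <- sobel_grad(f)
  strength <- function(g) sqrt(g$gx^2 + g$gy^2)
  orient <- function(g) {
    # atan of the component ratio; a vanishing x-component maps to pi/2
    # regardless of sign, keeping the score negation-invariant
    al <- atan(g$gy / g$gx)
    al[g$gx == 0] <- pi / 2
    al
  }
  sig <- function(x, gamma, kappa, delta) {
    raw <- gamma / (1 + exp(kappa * (x - delta)))
    raw / (gamma / (1 + exp(kappa * (1 - delta)))) # = 1 at x = 1
  }
  qsf <- function(gs, gfu) {
    s_s <- strength(gs); s_f <- strength(gfu)
    hi <- pmax(s_s, s_f); lo <- pmin(s_s, s_f)
    G <- ifelse(hi == 0, 1, lo / hi) # no edge anywhere: perfectly preserved
    A <- 1 - abs(orient(gs) - orient(gfu)) / (pi / 2)
    sig(G, 0.9994, -15, 0.5) * sig(A, 0.9879, -22, 0.8)
  }
  wa <- strength(ga)
  wb <- strength(gb)
  denom <- sum(wa + wb)
  if (denom == 0) return(0) # both sources constant: nothing to preserve
  sum(qsf(ga, gf) * wa + qsf(gb, gf) * wb) / denom
}

#' Full metric report for a fused triplet
#'
#' Assembles the nine quality scores into a one-row tibble with the
#' standard column names (API, SD, AG, Entropy, MIF, FS1, Corr, SF, QABF),
#' using the default variants of each component metric.
#'
#' @param f Fused image.
#' @param a,b Source images.
#' @param variant Optional label stored in a leading `variant` column.
#' @return A one-row [tibble::tibble].
#' @export
#' @examples
#' fx <- analytic_fixtures()
#' fusion_metrics(fx$checkerboard, fx$checkerboard, fx$checkerboard)
fusion_metrics <- function(f, a, b, variant = NULL) {
  check_same_shape(f, a)
  check_same_shape(f, b)
  row <- tibble::tibble(
    API = metric_api(f),
    SD = metric_sd(f),
    AG = metric_ag(f),
    Entropy = metric_entropy(f),
    MIF = metric_mif(f, a, b),
    FS1 = metric_fs1(f, a, b),
    Corr = metric_corr(f, a, b),
    SF = metric_sf(f),
    QABF = metric_qabf(f, a, b)
  )
  if (!is.null(variant)) {
    row <- tibble::add_column(row, variant = variant, .before = 1L)
  }
  row
}

#' Export a metric report table
#'
#' Writes one row per (fused, A, B) triplet as CSV or JSON, chosen by the
#' file extension (or the `format` argument).
#'
#' @param report Tibble/data frame as produced by [fusion_metrics()] or
#'   [ablation_suite()].
#' @param path Output file path.
#' @param format `"auto"` (default, by extension), `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
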