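#' Statistical test result container
#'
#' @param test Test name.
#' @param statistic Test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param n Sample size.
#' @param alpha Significance level used for the verdict.
#' @param verdict Optional character verdict.
#' @return A `stat_test_result`.
#' @export
stat_test_result <- function(test, statistic, p_value, n, alpha = 0.05,
                             verdict = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, alpha = alpha,
                 verdict = verdict %||%
                   if (p_value < alpha) "significant" else "not significant"),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, alpha = %g) -> %s\n",
              x$test, x$statistic, x$p_value, x$n, x$alpha, x$verdict))
  invisible(x)
}

#' Vessel-wall SNR
#'
#' The signal is the peak intensity within the vessel-wall region (intensity
#' peaks at the wall and decays rapidly into the lumen) and the noise is the
#' standard deviation within the vessel lumen: `SNR = peak_wall / sd_lumen`.
#' A `"p99"` peak estimator is available for robustness against single hot
#' pixels.
#'
#' @param image A [gray_image()] or matrix.
#' @param wall_roi,lumen_roi Logical masks.
#' @param peak `"max"` (default) or `"p99"` (99th percentile).
#' @return List with `signal`, `noise`, `snr`.
#' @export
snr_vessel_wall <- function(image, wall_roi, lumen_roi, peak = c("max", "p99")) {
  peak <- match.arg(peak)
  w <- roi_pixels(image, wall_roi)
  l <- roi_pixels(image, lumen_roi)
  if (length(w) < 1L || length(l) < 4L)
    mrd_error("wall ROI must be non-empty and lumen ROI have >= 4 pixels",
              "mrd_roi_error")
  signal <- if (peak == "max") max(w) else unname(quantile(w, 0.99))
  noise <- stats::sd(l)
  if (noise == 0)
    mrd_error("lumen standard deviation is zero: SNR undefined",
              "mrd_undefined_snr_error")
  list(signal = signal, noise = noise, snr = signal / noise)
}

#' Region SNR
#'
#' Signal and noise measured as the mean and standard deviation of one ROI
#' (used for CSF and parenchyma, where noise cannot be measured in the air
#' because parallel-imaging noise is spatially inhomogeneous):
#' `SNR = mean / sd`.
#'
#' @param image A [gray_image()] or matrix.
#' @param roi Logical mask with at least 4 pixels.
#' @return List with `signal`, `noise`, `snr`.
#' @export
snr_region <- function(image, roi) {
  v <- roi_pixels(image, roi)
  if (length(v) < 4L)
    mrd_error("ROI must have at least 4 pixels", "mrd_roi_error")
  noise <- stats::sd(v)
  if (noise == 0)
    mrd_error("ROI standard deviation is zero: SNR undefined",
              "mrd_undefined_snr_error")
  list(signal = mean(v), noise = noise, snr = mean(v) / noise)
}

#' Blockwise noise map
#'
#' Sample standard deviation in every non-overlapping `window x window` tile
#' (default 5 x 5); edge remainders are dropped. Constant images map to all
#' zeros.
#'
#' @param image A [gray_image()] or matrix.
#' @param window Odd tile side >= 3.
#' @return A `noise_map`: numeric matrix of per-tile standard deviations with
#'   attribute `window`.
#' @export
noise_map <- function(image, window = 5L) {
  if (window %% 2L != 1L || window < 3L)
    mrd_error("window must be odd and >= 3", "mrd_parameter_error")
  px <- as_pixel_matrix(image)
  nbr <- nrow(px) %/% window
  nbc <- ncol(px) %/% window
  if (nbr < 1L || nbc < 1L)
    mrd_error("image smaller than one tile", "mrd_shape_error")
  px <- px[seq_len(nbr * window), seq_len(nbc * window)]
  a <- array(px, c(window, nbr, window, nbc))
  m1 <- apply(a, c(2, 4), mean)
  m2 <- apply(a, c(2, 4), function(v) mean(v^2))
  n <- window^2
  v <- pmax((m2 - m1^2) * n / (n - 1), 0)
  structure(sqrt(v), window = window, class = c("noise_map", class(matrix())))
}

# --- BRISQUE ---------------------------------------------------------------

# Gaussian weighting window used for local MSCN statistics (7 x 7, sd 7/6).
mscn_kernel <- function() {
  r <- 3L
  g <- exp(-(seq(-r, r))^2 / (2 * (7 / 6)^2))
  k <- outer(g, g)
  k / sum(k)
}

filter2_same <- function(x, k) {
  # 'same' correlation with replicated edges (k is symmetric here)
  r <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(nr), rep(nr, r)),
          c(rep(1L, r), seq_len(nc), rep(nc, r))]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k)))
    for (j in seq_len(ncol(k)))
      if (k[i, j] != 0)
        out <- out + k[i, j] * xp[i:(i + nr - 1L), j:(j + nc - 1L)]
  out
}

mscn_coefficients <- function(px, C = 1) {
  k <- mscn_kernel()
  mu <- filter2_same(px, k)
  sigma <- sqrt(pmax(0, filter2_same(px^2, k) - mu^2))
  (px - mu) / (sigma + C)
}

# Moment-matching fit of the generalised Gaussian shape parameter.
ggd_fit <- function(x) {
  s2 <- mean(x^2)
  if (s2 == 0)
    mrd_error("degenerate MSCN statistics (constant image?)", "mrd_degenerate_error")
  rho <- mean(abs(x))^2 / s2
  gam <- seq(0.2, 10, by = 0.001)
  r <- (gamma(2 / gam))^2 / (gamma(1 / gam) * gamma(3 / gam))
  alpha <- gam[which.min(abs(rho - r))]
  c(shape = alpha, variance = s2)
}

# Asymmetric generalised Gaussian fit (the standard BRISQUE estimator).
aggd_fit <- function(x) {
  xl <- x[x < 0]; xr <- x[x >= 0]
  sl <- if (length(xl)) sqrt(mean(xl^2)) else 0
  sr <- if (length(xr)) sqrt(mean(xr^2)) else 0
  if (sl == 0 || sr == 0)
    mrd_error("degenerate paired-product statistics", "mrd_degenerate_error")
  gammahat <- sl / sr
  rhat <- mean(abs(x))^2 / mean(x^2)
  Rhat <- rhat * (gammahat^3 + 1) * (gammahat + 1) / (gammahat^2 + 1)^2
  gam <- seq(0.2, 10, by = 0.001)
  r <- (gamma(2 / gam))^2 / (gamma(1 / gam) * gamma(3 / gam))
  alpha <- gam[which.min(abs(Rhat - r))]
  eta <- (sr - sl) * gamma(2 / alpha) / sqrt(gamma(1 / alpha) * gamma(3 / alpha))
  c(shape = alpha, mean = eta, left_var = sl^2, right_var = sr^2)
}

#' BRISQUE natural-scene-statistics features
#'
#' Extracts the 36 BRISQUE features: at each of two scales, a 2-parameter
#' generalised-Gaussian fit of the MSCN (mean-subtracted
#' contrast-normalised) coefficients plus 4-parameter asymmetric
#' generalised-Gaussian fits of the four orientation pairwise products
#' (horizontal, vertical, two diagonals). Intensities are rescaled to
#' `[0, 255]` first; the MSCN stabilising constant is 1 on that scale.
#'
#' @param image A [gray_image()] or matrix, at least 32 x 32.
#' @return Named numeric vector of length 36.
#' @export
brisque_features <- function(image) {
  px <- as_pixel_matrix(image)
  if (nrow(px) < 32L || ncol(px) < 32L)
    mrd_error("image must be at least 32x32", "mrd_shape_error")
  rng <- range(px)
  if (rng[1] == rng[2])
    mrd_error("constant image: BRISQUE features are degenerate",
              "mrd_degenerate_error")
  px <- (px - rng[1]) / (rng[2] - rng[1]) * 255
  feats <- c()
  for (scale in 1:2) {
    m <- mscn_coefficients(px)
    f <- ggd_fit(as.vector(m))
    names(f) <- paste0("s", scale, "_mscn_", c("shape", "variance"))
    feats <- c(feats, f)
    shifts <- list(h = m[, -1] * m[, -ncol(m)],
                   v = m[-1, ] * m[-nrow(m), ],
                   d1 = m[-1, -1] * m[-nrow(m), -ncol(m)],
                   d2 = m[-1, -ncol(m)] * m[-nrow(m), -1])
    for (o in names(shifts)) {
      f <- aggd_fit(as.vector(shifts[[o]]))
      names(f) <- paste0("s", scale, "_", o, "_", names(f))
      feats <- c(feats, f)
    }
    if (scale == 1L)
      px <- as.matrix(EBImage::resize(px, w = floor(nrow(px) / 2),
                                      h = floor(ncol(px) / 2)))
  }
  if (!all(is.finite(feats)))
    mrd_error("non-finite BRISQUE features", "mrd_degenerate_error")
  feats
}

#' Fit the fallback BRISQUE scorer on a pristine corpus
#'
#' The reference BRISQUE score uses a pretrained support-vector regressor;
#' when such a model file is not supplied, this self-contained scorer maps
#' the standardised distance between an image's BRISQUE features and a
#' user-provided corpus of clean images to `[0, 100]`. Scores are comparable
#' only within one corpus.
#'
#' @param clean_images List of clean [gray_image()]s (>= 3).
#' @return A `brisque_scorer`.
#' @export
fit_brisque_scorer <- function(clean_images) {
  if (length(clean_images) < 3L)
    mrd_error("need at least 3 pristine images", "mrd_configuration_error")
  F <- t(vapply(clean_images, brisque_features, numeric(36)))
  mu <- colMeans(F)
  sdv <- pmax(apply(F, 2, stats::sd), 1e-8)
  d <- apply(F, 1, function(f) sqrt(mean(((f - mu) / sdv)^2)))
  structure(list(mu = mu, sd = sdv, d0 = max(stats::median(d), 1e-6),
                 n_corpus = nrow(F)),
            class = "brisque_scorer")
}

#' BRISQUE quality score
#'
#' Maps BRISQUE features to a quality score in `[0, 100]` (lower is better).
#' With a fitted [fit_brisque_scorer()] the score is
#' `100 * d / (d + d0)` where `d` is the standardised feature distance to
#' the pristine corpus and `d0` the corpus' median self-distance — strictly
#' increasing in the distance, 0 at the corpus centre, asymptotically 100.
#'
#' @param features A 36-vector from [brisque_features()], or an image.
#' @param scorer A `brisque_scorer`.
#' @return Score in `[0, 100]`.
#' @export
brisque_score <- function(features, scorer) {
  if (missing(scorer) || is.null(scorer))
    mrd_error("no scorer configured: supply a fitted brisque_scorer",
              "mrd_configuration_error")
  if (is.matrix(features) || inherits(features, "gray_image"))
    features <- brisque_features(features)
  d <- sqrt(mean(((features - scorer$mu) / scorer$sd)^2))
  min(100, max(0, 100 * d / (d + scorer$d0)))
}

#' Paired t test
#'
#' Two-sided paired t test with significance assessed at `alpha` (default
#' 0.05). All-zero differences are signalled as a degenerate-variance error
#' rather than returned silently.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 3).
#' @param alpha Significance level.
#' @return A [stat_test_result()].
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3L)
    mrd_error("x and y must be paired with n >= 3", "mrd_parameter_error")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(stat_test_result("paired-t", 0, 1, length(x), alpha,
                              verdict = "no difference"))
    mrd_error("differences have zero variance: t statistic undefined",
              "mrd_degenerate_error")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_test_result("paired-t", tt$statistic, tt$p.value, length(x), alpha)
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS test of `x` against a normal distribution with the sample
#' mean and standard deviation, the normality screen applied before the
#' paired comparisons.
#'
#' @param x Numeric vector (n >= 3).
#' @param alpha Significance level (default 0.05).
#' @return A [stat_test_result()] with verdict `"normal"`/`"not normal"`.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  if (length(x) < 3L)
    mrd_error("need at least 3 observations", "mrd_parameter_error")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  stat_test_result("Kolmogorov-Smirnov", kt$statistic, kt$p.value, length(x),
                   alpha,
                   verdict = if (kt$p.value > alpha) "normal" else "not normal")
}

#' Per-region quality report
#'
#' Computes the full no-reference metric set for one image: vessel-wall SNR
#' (peak wall signal over lumen noise), CSF and parenchyma SNR (mean over
#' sd), and optionally a BRISQUE score and noise map.
#'
#' @param image A [gray_image()] or matrix.
#' @param roi An [roi_set()] with `vessel_wall`, `lumen`, `csf`,
#'   `parenchyma`.
#' @param scorer Optional `brisque_scorer`.
#' @param window Noise-map tile side (NULL to skip the map).
#' @return A `quality_report` list.
#' @export
quality_report <- function(image, roi, scorer = NULL, window = 5L) {
  vw <- snr_vessel_wall(image, roi$vessel_wall, roi$lumen)
  csf <- snr_region(image, roi$csf)
  par <- snr_region(image, roi$parenchyma)
  structure(list(
    vessel_wall = vw, csf = csf, parenchyma = par,
    brisque = if (!is.null(scorer)) brisque_score(image, scorer) else NA_real_,
    noise_map = if (!is.null(window)) noise_map(image, window) else NULL),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  for (r in c("vessel_wall", "csf", "parenchyma"))
    cat(sprintf("  %-12s signal %8.3f  noise %7.3f  SNR %7.3f\n",
                r, x[[r]]$signal, x[[r]]$noise, x[[r]]$snr))
  if (!is.na(x$brisque)) cat(sprintf("  BRISQUE %.2f\n", x$brisque))
  invisible(x)
}
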