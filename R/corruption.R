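#' Additive noise specification
#'
#' Describes the artificial corruption model used to build pixel-aligned
#' training pairs: zero-mean Gaussian noise whose standard deviation is a
#' per-image uniform draw from `sigma_frac_range` times the image's
#' arithmetic mean. The default range (0.25, 0.35) is the range reported to
#' give the best denoising performance for this class of images; a Rician
#' family and a smooth multiplicative inhomogeneity field on sigma
#' (parallel-imaging-like spatially varying noise) are optional.
#'
#' @param mu Noise mean (default 0; must be 0 for the Rician family).
#' @param sigma_frac_range Length-2 range of sigma as a fraction of the image
#'   arithmetic mean.
#' @param family `"gaussian"` (additive) or `"rician"` (magnitude of the
#'   complex signal with Gaussian noise on both channels).
#' @param inhomogeneity `NULL` for spatially uniform noise, or a list
#'   `list(amplitude=, corr_len=)` describing a smooth multiplicative field
#'   applied to sigma (mean 1, standard deviation `amplitude`).
#' @param clip If `TRUE`, clip the output at 0 (off by default; corrupted
#'   images may dip below 0).
#' @param seed Integer seed.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(mu = 0, sigma_frac_range = c(0.25, 0.35),
                       family = c("gaussian", "rician"),
                       inhomogeneity = NULL, clip = FALSE, seed = NULL) {
  family <- match.arg(family)
  if (length(sigma_frac_range) == 1L)
    sigma_frac_range <- rep(sigma_frac_range, 2L)
  if (sigma_frac_range[1] < 0 || sigma_frac_range[1] > sigma_frac_range[2])
    mrd_error("sigma_frac_range must satisfy 0 <= low <= high", "mrd_parameter_error")
  if (!is.finite(mu))
    mrd_error("mu must be finite", "mrd_parameter_error")
  if (family == "rician" && mu != 0)
    mrd_error("the Rician family requires mu = 0 (noise enters the magnitude, not the mean)",
              "mrd_parameter_error")
  structure(list(mu = mu, sigma_frac_range = sigma_frac_range, family = family,
                 inhomogeneity = inhomogeneity, clip = clip, seed = seed),
            class = "noise_spec")
}

#' Corrupt an image with the artificial noise model
#'
#' Adds `g(mu, sigma)` noise to the image, with sigma drawn uniformly
#' (per image) from `sigma_frac_range` times the image's arithmetic mean.
#' The sigma actually used is attached as attribute `"sigma"`.
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param spec A [noise_spec()].
#' @return The corrupted [gray_image()] (not clipped unless `spec$clip`).
#' @export
add_noise <- function(image, spec = noise_spec()) {
  stopifnot(inherits(spec, "noise_spec"))
  px <- as_pixel_matrix(image)
  with_seed(spec$seed, {
    frac <- runif(1, spec$sigma_frac_range[1], spec$sigma_frac_range[2])
    sigma <- frac * mean(px)
    if (sigma == 0) {
      out <- px
    } else {
      sig_map <- sigma
      if (!is.null(spec$inhomogeneity)) {
        f <- gaussian_field(nrow(px), ncol(px), spec$inhomogeneity$corr_len %||% 8)
        sig_map <- sigma * pmax(0, 1 + (spec$inhomogeneity$amplitude %||% 0.5) * f)
      }
      if (spec$family == "gaussian") {
        out <- px + spec$mu + matrix(rnorm(length(px)), nrow(px)) * sig_map
      } else {
        n1 <- matrix(rnorm(length(px)), nrow(px)) * sig_map
        n2 <- matrix(rnorm(length(px)), nrow(px)) * sig_map
        out <- sqrt((px + n1)^2 + n2^2)
      }
      if (spec$clip) out <- pmax(out, 0)
    }
    res <- reimage(if (inherits(image, "gray_image")) image else
      gray_image(px, check = FALSE), out)
    attr(res, "sigma") <- sigma
    res
  })
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus test combining the transformed sample skewness and
#' kurtosis statistics; K2 = Zs^2 + Zk^2 is referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector, n >= 20 (the skewness/kurtosis normal
#'   approximations are unreliable below that).
#' @param alpha Significance level for the verdict (default 0.01, the level
#'   at which air noise is deemed Gaussian-modellable).
#' @return A `stat_test_result` with fields `test`, `statistic`, `p_value`,
#'   `n`, `alpha`, `verdict` (`"normal"` if `p_value > alpha`).
#' @export
dagostino_pearson <- function(x, alpha = 0.01) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L)
    mrd_error("D'Agostino-Pearson test requires at least 20 observations",
              "mrd_sample_size_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    mrd_error("degenerate sample: zero variance", "mrd_degenerate_error")
  b1 <- mean((x - m)^3) / m2^1.5     # sample skewness g1
  b2 <- mean((x - m)^4) / m2^2       # sample kurtosis g2 (non-excess)

  # Skewness: D'Agostino (1970) transformation to normality
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha_s <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha_s + sqrt((Y / alpha_s)^2 + 1))

  # Kurtosis: Anscombe & Glynn (1983) transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqrtB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtB1 * (2 / sqrtB1 + sqrt(1 + 4 / sqrtB1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Zs^2 + Zk^2
  p <- stats::pchisq(K2, df = 2, lower.tail = FALSE)
  stat_test_result("D'Agostino-Pearson", K2, p, n, alpha,
                   verdict = if (p > alpha) "normal" else "not normal")
}

#' Estimate noise from an air region
#'
#' Estimates the noise standard deviation as the sample standard deviation of
#' the intensities inside an air region (for example, a 10 x 10 air box), and
#' tests whether the noise is Gaussian-modellable with the
#' D'Agostino-Pearson omnibus test: the additive Gaussian corruption model is
#' considered adequate when the normality p-value exceeds 0.01.
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param air_roi Logical mask of the air region.
#' @param alpha Verdict level (default 0.01).
#' @return List with `sigma` and `normality` (a `stat_test_result`).
#' @export
estimate_air_noise <- function(image, air_roi, alpha = 0.01) {
  v <- roi_pixels(image, air_roi)
  v <- v[is.finite(v)]
  if (length(v) < 20L)
    mrd_error("air ROI must contain at least 20 valid pixels",
              "mrd_sample_size_error")
  if (stats::sd(v) == 0)
    mrd_error("air ROI is constant: moments are degenerate", "mrd_degenerate_error")
  list(sigma = stats::sd(v), normality = dagostino_pearson(v, alpha = alpha))
}

#' Variable-density Poisson-disk k-space sampling mask
#'
#' Builds a 2-D k-space sampling pattern via variable-density Poisson-disk
#' dart throwing: the local exclusion radius grows with distance from the
#' k-space centre (denser centre, as conventional in compressed-sensing MRI),
#' and a fully sampled central disk guarantees the DC frequency. The radius
#' scale is calibrated by bisection so the sampled fraction is within 10% of
#' `1/acceleration`.
#'
#' @param shape Length-2 integer mask size.
#' @param acceleration Target reciprocal sampling fraction (>= 1).
#' @param seed Integer seed.
#' @return A `sampling_mask`: logical matrix with attributes `acceleration`
#'   and `sampled_fraction`; centre (DC) always sampled.
#' @export
poisson_disk_mask <- function(shape, acceleration, seed = NULL) {
  if (acceleration < 1)
    mrd_error("acceleration must be >= 1", "mrd_parameter_error")
  if (length(shape) == 1L) shape <- c(shape, shape)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (acceleration == 1) {
    m <- matrix(TRUE, nr, nc)
  } else {
    m <- with_seed(seed, {
      cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
      I <- matrix(seq_len(nr), nr, nc)
      J <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      d <- sqrt(((I - cy) / (nr / 2))^2 + ((J - cx) / (nc / 2))^2)  # 0..~1.4
      centre <- d <= 0.08
      ord <- sample.int(nr * nc) - 1L
      target <- 1 / acceleration
      lo <- 0.1; hi <- 6
      mask <- NULL
      for (it in 1:24) {
        s <- (lo + hi) / 2
        r <- s * (0.4 + 2.6 * pmin(d, 1.2))
        mask <- pdisk_thin(nr, nc, ord, as.numeric(r)) | centre
        frac <- mean(mask)
        if (abs(frac - target) <= 0.05 * target) break
        if (frac > target) lo <- s else hi <- s
      }
      mask
    })
  }
  structure(m, acceleration = acceleration, sampled_fraction = mean(m),
            class = c("sampling_mask", class(matrix())))
}

#' Zero-filled reconstruction from undersampled k-space
#'
#' Transforms the image to k-space with a 2-D discrete Fourier transform,
#' zeroes the unsampled frequencies, and inverts the transform. The mask is
#' defined with the DC frequency at its centre. With a full mask the
#' operation is the identity. The default output is the magnitude image (the
#' conventional zero-filled reconstruction); `output = "complex"` or
#' `"real"` exposes the underlying linear k-space projection, which is
#' idempotent for a fixed mask.
#'
#' @param image A [gray_image()] or numeric/complex matrix.
#' @param mask A [poisson_disk_mask()] or logical matrix (DC at centre).
#' @param output `"magnitude"` (default), `"real"`, or `"complex"`.
#' @return A [gray_image()] (or a complex matrix for `output = "complex"`).
#' @export
zero_fill_reconstruct <- function(image, mask,
                                  output = c("magnitude", "real", "complex")) {
  output <- match.arg(output)
  px <- if (is.complex(image)) image else as_pixel_matrix(image)
  if (!identical(dim(px), dim(unclass(mask))))
    mrd_error("image and mask shapes differ", "mrd_shape_error")
  m <- ifftshift(unclass(mask))
  k <- stats::fft(px) * m
  rec <- stats::fft(k, inverse = TRUE) / length(k)
  out <- switch(output, magnitude = Mod(rec), real = Re(rec), complex = rec)
  if (output == "complex") return(out)
  reimage(if (inherits(image, "gray_image")) image else gray_image(Re(px), check = FALSE),
          out)
}

# Move the centre pixel of a centred mask to position [1,1] (DC convention
# of the discrete Fourier transform).
ifftshift <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((floor(nr / 2) + 1L):nr, seq_len(floor(nr / 2)))
  ci <- c((floor(nc / 2) + 1L):nc, seq_len(floor(nc / 2)))
  m[ri, ci]
}
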