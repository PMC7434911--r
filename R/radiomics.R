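#' Radiomics configuration
#'
#' @param roi_size Target ROI size in pixels (default 1600, a 40 x 40
#'   parenchyma box).
#' @param bins Number of equal-width grey-level bins for discretisation
#'   (default 32).
#' @param wavelet Wavelet basis; only the orthonormal Haar basis (1 level)
#'   is implemented.
#' @return A `radiomics_config`.
#' @export
radiomics_config <- function(roi_size = 1600L, bins = 32L, wavelet = "haar") {
  if (bins < 2L) mrd_error("bins must be >= 2", "mrd_parameter_error")
  if (!identical(wavelet, "haar"))
    mrd_error("only the Haar wavelet is implemented", "mrd_parameter_error")
  structure(list(roi_size = as.integer(roi_size), bins = as.integer(bins),
                 wavelet = wavelet), class = "radiomics_config")
}

#' Discretise an ROI into grey-level bins
#'
#' Equal-width binning of the ROI intensities over their `[min, max]` range
#' into labels `1..bins`; pixels outside the ROI are `NA`.
#'
#' @param image A [gray_image()] or matrix.
#' @param roi Logical mask.
#' @param bins Number of bins.
#' @param strict Error on a constant ROI with `bins > 1` (default). With
#'   `strict = FALSE` a constant ROI is labelled all-1 with a warning.
#' @return Integer matrix of labels (`NA` outside the ROI).
#' @export
discretise <- function(image, roi, bins, strict = TRUE) {
  px <- as_pixel_matrix(image)
  v <- px[roi]
  lab <- matrix(NA_integer_, nrow(px), ncol(px))
  if (bins == 1L) {
    lab[roi] <- 1L
    return(lab)
  }
  rng <- range(v)
  if (rng[1] == rng[2]) {
    if (strict)
      mrd_error("ROI is constant: discretisation into >1 bins is undefined",
                "mrd_degenerate_error")
    mrd_warn("constant ROI: all pixels assigned to bin 1", "mrd_degenerate_warning")
    lab[roi] <- 1L
    return(lab)
  }
  l <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  l[l > bins] <- as.integer(bins)
  lab[roi] <- as.integer(l)
  lab
}

# Replace non-finite feature values (degenerate formulas, e.g. a single grey
# level) by 0, keeping tables rectangular.
sanitize_features <- function(f) {
  bad <- !is.finite(f)
  if (any(bad)) {
    mrd_warn(sprintf("%d degenerate feature value(s) set to 0: %s",
                     sum(bad), paste(names(f)[bad], collapse = ", ")),
             "mrd_degenerate_warning")
    f[bad] <- 0
  }
  f
}

#' First-order radiomic features
#'
#' The 18 standard first-order statistics of the ROI intensities and their
#' discretised histogram (energy, entropy, percentiles, robust deviations,
#' skewness, kurtosis, uniformity, ...).
#'
#' @param image A [gray_image()] or matrix.
#' @param roi Logical mask with >= 10 pixels.
#' @param bins Histogram bins for entropy/uniformity (default 32).
#' @param pixel_spacing Pixel size in mm (for total energy).
#' @return Named numeric vector of 18 features (prefix `firstorder_`).
#' @export
first_order_features <- function(image, roi, bins = 32L,
                                 pixel_spacing = attr(image, "pixel_spacing") %||% 0.4) {
  v <- roi_pixels(image, roi)
  if (length(v) < 10L)
    mrd_error("ROI must have at least 10 pixels", "mrd_roi_error")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  q <- unname(quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  inrange <- v[v >= q[1] & v <= q[5]]
  lab <- discretise(image, roi, bins, strict = FALSE)
  p <- tabulate(lab[roi], nbins = bins)
  p <- p / sum(p)
  pn <- p[p > 0]
  f <- c(
    Energy = sum(v^2),
    TotalEnergy = sum(v^2) * pixel_spacing^2,
    Entropy = -sum(pn * log2(pn)),
    Minimum = min(v),
    P10 = q[1],
    P90 = q[5],
    Maximum = max(v),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = mean(abs(inrange - mean(inrange))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  names(f) <- paste0("firstorder_", names(f))
  sanitize_features(f)
}

# --- grey-level matrix families --------------------------------------------

# Co-occurrence counts for one offset, symmetric.
glcm_matrix <- function(lab, dr, dc, G) {
  nr <- nrow(lab); nc <- ncol(lab)
  ri <- seq_len(nr); ci <- seq_len(nc)
  vi <- ri[ri + dr >= 1 & ri + dr <= nr]
  vj <- ci[ci + dc >= 1 & ci + dc <= nc]
  a <- lab[vi, vj, drop = FALSE]
  b <- lab[vi + dr, vj + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  P <- matrix(0, G, G)
  if (any(ok)) {
    t <- table(factor(a[ok], levels = seq_len(G)),
               factor(b[ok], levels = seq_len(G)))
    P[] <- as.numeric(unclass(t) + t(unclass(t)))
    dimnames(P) <- NULL
  }
  P
}

glcm_features_one <- function(P) {
  G <- nrow(P)
  s <- sum(P)
  if (s == 0) return(rep(NaN, 24))
  p <- P / s
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p)
  ux <- sum(seq_len(G) * px)
  sx <- sqrt(sum((seq_len(G) - ux)^2 * px))
  # difference and sum distributions
  pd <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ps <- vapply(2:(2 * G), function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum((0:(G - 1)) * pd)
  pdn <- pd[pd > 0]; psn <- ps[ps > 0]; ppn <- p[p > 0]
  hxy <- -sum(ppn * log2(ppn))
  pxpy <- outer(px, px)
  w <- p > 0 & pxpy > 0
  hxy1 <- -sum(p[w] * log2(pxpy[w]))
  w2 <- pxpy > 0
  hxy2 <- -sum(pxpy[w2] * log2(pxpy[w2]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  # MCC: second-largest eigenvalue of the Markov-like transition matrix
  mcc <- tryCatch({
    py <- colSums(p)
    Q <- matrix(0, G, G)
    nz <- which(px > 0)
    for (a in nz) {
      denom <- px[a] * py
      ok <- denom > 0
      Q[a, nz] <- vapply(nz, function(bq)
        sum(p[a, ok] * p[bq, ok] / denom[ok]), numeric(1))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2 && ev[2] > 0) sqrt(ev[2]) else 0
  }, error = function(e) NaN)
  c(glcm_Autocorrelation = sum(i * j * p),
    glcm_ClusterProminence = sum((i + j - 2 * ux)^4 * p),
    glcm_ClusterShade = sum((i + j - 2 * ux)^3 * p),
    glcm_ClusterTendency = sum((i + j - 2 * ux)^2 * p),
    glcm_Contrast = sum((i - j)^2 * p),
    glcm_Correlation = if (sx > 0) (sum(i * j * p) - ux^2) / sx^2 else NaN,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pdn * log2(pdn)),
    glcm_DifferenceVariance = sum(((0:(G - 1)) - da)^2 * pd),
    glcm_Id = sum(p / (1 + abs(i - j))),
    glcm_Idm = sum(p / (1 + (i - j)^2)),
    glcm_Idmn = sum(p / (1 + (i - j)^2 / G^2)),
    glcm_Idn = sum(p / (1 + abs(i - j) / G)),
    glcm_Imc1 = if (hx > 0) (hxy - hxy1) / hx else NaN,
    glcm_Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    glcm_InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    glcm_JointAverage = ux,
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = hxy,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(p),
    glcm_SumAverage = sum((2:(2 * G)) * ps),
    glcm_SumEntropy = -sum(psn * log2(psn)),
    glcm_SumSquares = sum((i - ux)^2 * p))
}

glcm_features <- function(lab, G) {
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  fs <- vapply(offsets, function(o)
    glcm_features_one(glcm_matrix(lab, o[1], o[2], G)), numeric(24))
  out <- rowMeans(fs)
  names(out) <- rownames(fs)
  out
}

# Runs of equal labels along the four 2-D directions.
glrlm_runs <- function(lab) {
  lines <- c(
    split(lab, row(lab)),                 # horizontal (along columns)
    split(lab, col(lab)),                 # vertical
    split(lab, row(lab) + col(lab)),      # one diagonal
    split(lab, row(lab) - col(lab)))      # other diagonal
  nlines <- c(nrow(lab), ncol(lab),
              nrow(lab) + ncol(lab) - 1L, nrow(lab) + ncol(lab) - 1L)
  dir_id <- rep(1:4, nlines)
  list(lines = lines, dir = dir_id)
}

glrlm_matrix_dir <- function(lines, G) {
  gl <- integer(0); rl <- integer(0)
  for (ln in lines) {
    r <- rle(as.vector(ln))
    keep <- !is.na(r$values)
    gl <- c(gl, r$values[keep])
    rl <- c(rl, r$lengths[keep])
  }
  if (!length(gl)) return(matrix(0, G, 1))
  Rmax <- max(rl)
  P <- matrix(0, G, Rmax)
  for (k in seq_along(gl)) P[gl[k], rl[k]] <- P[gl[k], rl[k]] + 1
  P
}

# Shared run-length / size-zone statistics: P[g, s] counts of runs (zones)
# of grey level g and length (size) s.
rl_type_features <- function(P, Np, prefix, size_names) {
  Nr <- sum(P)
  if (Nr == 0) {
    f <- rep(NaN, 16)
  } else {
    G <- nrow(P); S <- ncol(P)
    g <- matrix(seq_len(G), G, S)
    s <- matrix(seq_len(S), G, S, byrow = TRUE)
    p <- P / Nr
    mu_g <- sum(g * p); mu_s <- sum(s * p)
    pn <- p[p > 0]
    f <- c(sum(P / s^2) / Nr,                    # short emphasis
           sum(P * s^2) / Nr,                    # long emphasis
           sum(rowSums(P)^2) / Nr,               # grey-level non-uniformity
           sum(rowSums(P)^2) / Nr^2,             # ... normalised
           sum(colSums(P)^2) / Nr,               # size non-uniformity
           sum(colSums(P)^2) / Nr^2,             # ... normalised
           Nr / Np,                              # percentage
           sum((g - mu_g)^2 * p),                # grey-level variance
           sum((s - mu_s)^2 * p),                # size variance
           -sum(pn * log2(pn)),                  # entropy
           sum(P / g^2) / Nr,                    # low grey-level
           sum(P * g^2) / Nr,                    # high grey-level
           sum(P / (g^2 * s^2)) / Nr,
           sum(P * g^2 / s^2) / Nr,
           sum(P * s^2 / g^2) / Nr,
           sum(P * s^2 * g^2) / Nr)
  }
  names(f) <- paste0(prefix, c(
    paste0("Short", size_names, "Emphasis"),
    paste0("Long", size_names, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(size_names, "NonUniformity"),
    paste0(size_names, "NonUniformityNormalized"),
    paste0(size_names, "Percentage"),
    "GrayLevelVariance", paste0(size_names, "Variance"),
    paste0(size_names, "Entropy"),
    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    paste0("Short", size_names, "LowGrayLevelEmphasis"),
    paste0("Short", size_names, "HighGrayLevelEmphasis"),
    paste0("Long", size_names, "LowGrayLevelEmphasis"),
    paste0("Long", size_names, "HighGrayLevelEmphasis")))
  f
}

glrlm_features <- function(lab, G) {
  Np <- sum(!is.na(lab))
  rr <- glrlm_runs(lab)
  fs <- vapply(1:4, function(d)
    rl_type_features(glrlm_matrix_dir(rr$lines[rr$dir == d], G), Np,
                     "glrlm_", "Run"), numeric(16))
  out <- rowMeans(fs)
  names(out) <- rownames(fs)
  out
}

glszm_features <- function(lab, G) {
  Np <- sum(!is.na(lab))
  m <- lab
  m[is.na(m)] <- 0L
  comp <- label8(m)
  ids <- comp[comp > 0]
  sizes <- tabulate(ids)
  # grey level of each zone = value at the first pixel of that label
  first <- match(seq_len(max(comp)), comp)
  greys <- m[first]
  Smax <- max(sizes)
  P <- matrix(0, G, Smax)
  for (k in seq_along(sizes)) P[greys[k], sizes[k]] <- P[greys[k], sizes[k]] + 1
  rl_type_features(P, Np, "glszm_",
                   size_names = "Zone") |> rename_szm()
}

# GLSZM uses Small/Large area instead of Short/Long run in its canonical names.
rename_szm <- function(f) {
  names(f) <- gsub("Short", "Small", names(f), fixed = TRUE)
  names(f) <- gsub("Long", "Large", names(f), fixed = TRUE)
  names(f) <- gsub("SmallZone", "SmallArea", names(f), fixed = TRUE)
  names(f) <- gsub("LargeZone", "LargeArea", names(f), fixed = TRUE)
  names(f) <- gsub("^glszm_ZoneNonUniformity", "glszm_SizeZoneNonUniformity",
                   names(f))
  f
}

# neighbour sums within Chebyshev distance 1 (NA-aware)
neighbour_stats <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  val <- lab; val[is.na(val)] <- 0
  ok <- !is.na(lab)
  sumn <- matrix(0, nr, nc); cntn <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sr <- max(1, 1 + dr):min(nr, nr + dr)
    tr <- max(1, 1 - dr):min(nr, nr - dr)
    sc <- max(1, 1 + dc):min(nc, nc + dc)
    tc <- max(1, 1 - dc):min(nc, nc - dc)
    sumn[tr, tc] <- sumn[tr, tc] + val[sr, sc] * ok[sr, sc]
    cntn[tr, tc] <- cntn[tr, tc] + ok[sr, sc]
  }
  list(sum = sumn, count = cntn)
}

ngtdm_features <- function(lab, G) {
  ns <- neighbour_stats(lab)
  use <- !is.na(lab) & ns$count > 0
  gv <- lab[use]
  avg <- ns$sum[use] / ns$count[use]
  N <- sum(use)
  s_i <- vapply(seq_len(G), function(g) sum(abs(gv[gv == g] - avg[gv == g])),
                numeric(1))
  n_i <- tabulate(gv, nbins = G)
  p_i <- n_i / N
  nz <- which(p_i > 0)
  Ngp <- length(nz)
  ii <- matrix(nz, Ngp, Ngp); jj <- t(ii)
  pi_ <- p_i[nz]
  pmat_i <- matrix(pi_, Ngp, Ngp); pmat_j <- t(pmat_i)
  smat_i <- matrix(s_i[nz], Ngp, Ngp); smat_j <- t(smat_i)
  coarse_den <- sum(p_i * s_i)
  contrast <- if (Ngp > 1)
    sum(pmat_i * pmat_j * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(s_i) / N
  else NaN
  busy_den <- sum(abs(ii * pmat_i - jj * pmat_j))
  f <- c(ngtdm_Coarseness = if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6,
         ngtdm_Contrast = contrast,
         ngtdm_Busyness = if (busy_den > 0) coarse_den / busy_den else NaN,
         ngtdm_Complexity = sum(abs(ii - jj) *
                                  (pmat_i * smat_i + pmat_j * smat_j) /
                                  (pmat_i + pmat_j)) / N,
         ngtdm_Strength = if (coarse_den > 0)
           sum((pmat_i + pmat_j) * (ii - jj)^2) / coarse_den else NaN)
  f
}

gldm_features <- function(lab, G) {
  nr <- nrow(lab); nc <- ncol(lab)
  ok <- !is.na(lab)
  dep <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sr <- max(1, 1 + dr):min(nr, nr + dr)
    tr <- max(1, 1 - dr):min(nr, nr - dr)
    sc <- max(1, 1 + dc):min(nc, nc + dc)
    tc <- max(1, 1 - dc):min(nc, nc - dc)
    eq <- ok[sr, sc] & ok[tr, tc] &
      lab[sr, sc] == lab[tr, tc]
    eq[is.na(eq)] <- FALSE
    dep[tr, tc] <- dep[tr, tc] + eq
  }
  g <- lab[ok]; d <- dep[ok] + 1L  # dependence count 0..8 -> column 1..9
  P <- matrix(0, G, 9L)
  for (k in seq_along(g)) P[g[k], d[k]] <- P[g[k], d[k]] + 1
  P <- P[, seq_len(max(d)), drop = FALSE]
  Nz <- sum(P)
  gm <- matrix(seq_len(G), G, ncol(P))
  jm <- matrix(seq_len(ncol(P)), G, ncol(P), byrow = TRUE)
  p <- P / Nz
  mu_g <- sum(gm * p); mu_j <- sum(jm * p)
  pn <- p[p > 0]
  f <- c(gldm_SmallDependenceEmphasis = sum(P / jm^2) / Nz,
         gldm_LargeDependenceEmphasis = sum(P * jm^2) / Nz,
         gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
         gldm_DependenceNonUniformity = sum(colSums(P)^2) / Nz,
         gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
         gldm_GrayLevelVariance = sum((gm - mu_g)^2 * p),
         gldm_DependenceVariance = sum((jm - mu_j)^2 * p),
         gldm_DependenceEntropy = -sum(pn * log2(pn)),
         gldm_LowGrayLevelEmphasis = sum(P / gm^2) / Nz,
         gldm_HighGrayLevelEmphasis = sum(P * gm^2) / Nz,
         gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (gm^2 * jm^2)) / Nz,
         gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * gm^2 / jm^2) / Nz,
         gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * jm^2 / gm^2) / Nz,
         gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * jm^2 * gm^2) / Nz)
  f
}

#' Texture features of one family
#'
#' Computes the standard derived statistics of one grey-level matrix family
#' on a discretised ROI: GLCM (24 features, symmetric matrix averaged over
#' the four 2-D angles), GLRLM (16, averaged over four directions), GLSZM
#' (16, zones by 8-connectivity), NGTDM (5) and GLDM (14), for 75 texture
#' features in total. Features whose formula is degenerate for the input
#' (e.g. a single grey level) are emitted as 0 with a warning.
#'
#' @param labelled_roi Integer label matrix from [discretise()].
#' @param family One of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @param n_levels Number of grey levels (defaults to the maximum label).
#' @return Named numeric vector.
#' @export
texture_features <- function(labelled_roi,
                             family = c("glcm", "glrlm", "glszm", "ngtdm", "gldm"),
                             n_levels = NULL) {
  family <- match.arg(family)
  G <- n_levels %||% max(labelled_roi, na.rm = TRUE)
  f <- switch(family,
              glcm = glcm_features(labelled_roi, G),
              glrlm = glrlm_features(labelled_roi, G),
              glszm = glszm_features(labelled_roi, G),
              ngtdm = ngtdm_features(labelled_roi, G),
              gldm = gldm_features(labelled_roi, G))
  sanitize_features(f)
}

#' Single-level Haar wavelet sub-bands
#'
#' Orthonormal single-level 2-D Haar transform; each of the four half-size
#' sub-bands is named by its row/column filters (`L` low-pass, `H`
#' high-pass). The transform conserves energy: the band energies sum to the
#' image energy.
#'
#' @param image A [gray_image()] or matrix with even sides.
#' @return List with bands `LL`, `LH`, `HL`, `HH`.
#' @export
wavelet_subbands <- function(image) {
  px <- as_pixel_matrix(image)
  if (nrow(px) %% 2L || ncol(px) %% 2L)
    mrd_error("image sides must be even", "mrd_shape_error")
  odd_r <- seq(1L, nrow(px), by = 2L)
  odd_c <- seq(1L, ncol(px), by = 2L)
  L <- (px[odd_r, , drop = FALSE] + px[odd_r + 1L, , drop = FALSE]) / sqrt(2)
  H <- (px[odd_r, , drop = FALSE] - px[odd_r + 1L, , drop = FALSE]) / sqrt(2)
  list(LL = (L[, odd_c] + L[, odd_c + 1L]) / sqrt(2),
       LH = (L[, odd_c] - L[, odd_c + 1L]) / sqrt(2),
       HL = (H[, odd_c] + H[, odd_c + 1L]) / sqrt(2),
       HH = (H[, odd_c] - H[, odd_c + 1L]) / sqrt(2))
}

all_features_one <- function(px, roi, bins, spacing) {
  fo <- first_order_features(gray_image(px, pixel_spacing = spacing, check = FALSE),
                             roi, bins = bins, pixel_spacing = spacing)
  lab <- discretise(px, roi, bins, strict = FALSE)
  tex <- c(texture_features(lab, "glcm", bins),
           texture_features(lab, "glrlm", bins),
           texture_features(lab, "glszm", bins),
           texture_features(lab, "ngtdm", bins),
           texture_features(lab, "gldm", bins))
  c(fo, tex)
}

#' Extract the full radiomic feature table
#'
#' For each image: 18 first-order + 75 texture features on the original
#' image, plus the same 93 on each of the four Haar sub-bands (ROI decimated
#' to the sub-band grid), for 465 columns in total. The same ROI must be used
#' for every condition of an image so that features are comparable.
#'
#' @param images Named list of [gray_image()]s / matrices (names become
#'   `image_id`s).
#' @param roi Logical mask (the common ROI; even-coordinate boxes recommended
#'   so the decimated ROI is exact).
#' @param config A [radiomics_config()].
#' @return A `feature_table`: data frame, rows = images, 465 feature columns.
#' @export
extract_feature_table <- function(images, roi, config = radiomics_config()) {
  if (is.null(names(images)))
    names(images) <- sprintf("img%03d", seq_along(images))
  roi_half <- roi[seq(1L, nrow(roi), 2L), seq(1L, ncol(roi), 2L)]
  rows <- lapply(images, function(im) {
    px <- as_pixel_matrix(im)
    spacing <- attr(im, "pixel_spacing") %||% 0.4
    f <- all_features_one(px, roi, config$bins, spacing)
    bands <- wavelet_subbands(px)
    for (b in names(bands)) {
      fb <- all_features_one(bands[[b]], roi_half, config$bins, spacing * 2)
      names(fb) <- paste0("wavelet-", b, "_", names(fb))
      f <- c(f, fb)
    }
    f
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments by default: agreement in both correlation and
#' scale/location.
#'
#' @param x,y Numeric vectors, equal length n >= 3, finite.
#' @param type `"population"` (1/n moments, default) or `"sample"`
#'   (1/(n-1)).
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y, type = c("population", "sample")) {
  type <- match.arg(type)
  if (length(x) != length(y) || length(x) < 3L)
    mrd_error("x and y must have equal length >= 3", "mrd_parameter_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    mrd_error("inputs must be finite", "mrd_parameter_error")
  n <- length(x)
  f <- if (type == "population") (n - 1) / n else 1
  vx <- stats::var(x) * f
  vy <- stats::var(y) * f
  cxy <- stats::cov(x, y) * f
  den <- vx + vy + (mean(x) - mean(y))^2
  if (den == 0)
    mrd_error("zero denominator: CCC undefined", "mrd_degenerate_error")
  2 * cxy / den
}

feature_class <- function(feature) {
  base <- sub("^wavelet-[A-Z]{2}_", "", feature)
  cls <- ifelse(grepl("^firstorder_", base), "first_order", "texture")
  ifelse(grepl("^wavelet-", feature), "wavelet", cls)
}

#' Radiomic reproducibility report
#'
#' Computes Lin's CCC per feature between two matched feature tables (for
#' example clean-reference vs denoised), flags features with CCC above the
#' reproducibility threshold (default 0.8), and summarises mean +/- sd CCC
#' and reproducible counts per feature class (first-order, texture,
#' wavelet). Features that are degenerate in both tables yield `NA` and are
#' excluded from class means.
#'
#' @param tableA,tableB `feature_table`s with identical columns and matched
#'   rows.
#' @param threshold Reproducibility threshold on CCC (default 0.8).
#' @return A `ccc_report` with `per_feature` and `summary` data frames.
#' @export
reproducibility_report <- function(tableA, tableB, threshold = 0.8) {
  if (!identical(colnames(tableA), colnames(tableB)))
    mrd_error("feature tables must have identical column sets", "mrd_parameter_error")
  if (nrow(tableA) != nrow(tableB))
    mrd_error("feature tables must have matched rows", "mrd_parameter_error")
  ccc <- vapply(colnames(tableA), function(f)
    tryCatch(lin_ccc(tableA[[f]], tableB[[f]]),
             mrdenoise_error = function(e) NA_real_), numeric(1))
  per_feature <- data.frame(feature = colnames(tableA),
                            class = feature_class(colnames(tableA)),
                            ccc = unname(ccc),
                            reproducible = unname(!is.na(ccc) & ccc > threshold),
                            row.names = NULL)
  cls <- split(per_feature, per_feature$class)
  summary <- do.call(rbind, lapply(names(cls), function(k) {
    d <- cls[[k]]
    data.frame(class = k,
               n = nrow(d),
               mean_ccc = mean(d$ccc, na.rm = TRUE),
               sd_ccc = stats::sd(d$ccc, na.rm = TRUE),
               n_reproducible = sum(d$reproducible),
               pct_reproducible = 100 * mean(d$reproducible),
               row.names = NULL)
  }))
  structure(list(per_feature = per_feature, summary = summary,
                 threshold = threshold),
            class = "ccc_report")
}

#' @export
print.ccc_report <- function(x, ...) {
  cat(sprintf("<ccc_report: %d features, reproducible = CCC > %.2g>\n",
              nrow(x$per_feature), x$threshold))
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-12s mean CCC %.2f +/- %.2f, %d/%d reproducible (%.1f%%)\n",
                s$class[k], s$mean_ccc[k], s$sd_ccc[k], s$n_reproducible[k],
                s$n[k], s$pct_reproducible[k]))
  invisible(x)
}
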