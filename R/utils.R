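# Internal helpers: classed errors, scoped RNG, smooth Gaussian random
# fields, bilinear resampling.

mrd_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mrdenoise_error", "error"),
                      call = call))
}

mrd_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mrdenoise_warning")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the R RNG, evaluates `expr`, and restores the previous RNG state so
#' that seeded generators do not disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 2147480000L
}

# Smooth zero-mean Gaussian random field: white noise low-pass filtered with
# an isotropic Gaussian kernel of standard deviation `corr_len` pixels, then
# rescaled to unit marginal standard deviation.
gaussian_field <- function(nr, nc, corr_len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len > 0) {
    z <- gauss_blur(z, corr_len)
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

# Separable Gaussian blur with replicated edges.
gauss_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, kern) {
    # filter columns of m with kern, edge replication
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(kern))
      out <- out + kern[t] * pad[t:(t + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x, k)), k))
}

# Bilinear sampling of matrix `img` at fractional coordinates (ri, ci),
# clamped to the image domain. ri, ci are matrices of target coordinates.
bilinear_sample <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(ri, 1), nr)
  ci <- pmin(pmax(ci, 1), nc)
  i0 <- pmin(floor(ri), nr - 1L); i1 <- i0 + 1L
  j0 <- pmin(floor(ci), nc - 1L); j1 <- j0 + 1L
  fi <- ri - i0; fj <- ci - j0
  v00 <- img[cbind(as.vector(i0), as.vector(j0))]
  v10 <- img[cbind(as.vector(i1), as.vector(j0))]
  v01 <- img[cbind(as.vector(i0), as.vector(j1))]
  v11 <- img[cbind(as.vector(i1), as.vector(j1))]
  out <- (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
    (1 - fi) * fj * v01 + fi * fj * v11
  matrix(out, nr, nc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
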