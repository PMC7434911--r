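# Neural-network engine: thin R layer over the RcppArmadillo kernels.
# A batch is a list of H x W x C arrays. All layers return forward caches
# sufficient for exact backpropagation; inference uses stored normalisation
# statistics so it is fully deterministic.

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

conv_fwd <- function(xs, W, b, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  nn_conv_fwd(xs, W, b, k, k, stride, pad)
}

conv_bwd <- function(xs, dys, W, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  nn_conv_bwd(xs, dys, W, k, k, stride, pad)
}

relu_fwd <- function(xs) nn_relu_fwd(xs)
relu_bwd <- function(dys, ys) nn_relu_bwd(dys, ys)

lrelu_fwd <- function(xs, slope = 0.2)
  lapply(xs, function(x) ifelse(x > 0, x, slope * x))
lrelu_bwd <- function(dys, xs, slope = 0.2)
  Map(function(d, x) d * ifelse(x > 0, 1, slope), dys, xs)

# --- batch normalisation (statistics over batch and space, per channel) ----

bn_fwd <- function(xs, gamma, beta, rm, rv, training, momentum = 0.1, eps = 1e-5) {
  r <- nn_bn_fwd(xs, gamma, beta, rm, rv, training, momentum, eps)
  list(y = r$y, cache = list(xhat = r$xhat, invstd = as.numeric(r$invstd)),
       rm = as.numeric(r$rm), rv = as.numeric(r$rv))
}

bn_bwd <- function(dys, cache, gamma) {
  r <- nn_bn_bwd(dys, cache$xhat, cache$invstd, gamma)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# --- instance normalisation (per sample, per channel) ----------------------

in_fwd <- function(xs, gamma, beta, eps = 1e-5) {
  caches <- vector("list", length(xs))
  ys <- vector("list", length(xs))
  for (n in seq_along(xs)) {
    x <- xs[[n]]; d <- dim(x)
    m <- matrix(x, ncol = d[3])
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
    y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    ys[[n]] <- array(y, d)
    caches[[n]] <- list(xhat = xhat, invstd = invstd, d = d)
  }
  list(y = ys, cache = caches)
}

in_bwd <- function(dys, cache, gamma) {
  dxs <- vector("list", length(dys))
  dgamma <- 0; dbeta <- 0
  for (n in seq_along(dys)) {
    cc <- cache[[n]]
    dm <- matrix(dys[[n]], ncol = cc$d[3])
    np <- nrow(dm)
    dg <- colSums(dm * cc$xhat); db <- colSums(dm)
    dgamma <- dgamma + dg; dbeta <- dbeta + db
    t1 <- sweep(dm, 2, db / np, "-")
    t2 <- sweep(cc$xhat, 2, dg / np, "*")
    dxs[[n]] <- array(sweep(t1 - t2, 2, gamma * cc$invstd, "*"), cc$d)
  }
  list(dx = dxs, dgamma = dgamma, dbeta = dbeta)
}

# --- channel concatenation --------------------------------------------------

cat_channels <- function(as, bs) {
  Map(function(a, b) {
    d <- dim(a)
    array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
  }, as, bs)
}

split_channels <- function(ds, c1) {
  list(lapply(ds, function(d) d[, , seq_len(c1), drop = FALSE]),
       lapply(ds, function(d) d[, , -seq_len(c1), drop = FALSE]))
}

# --- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.numeric(p)) list(m = p * 0, v = p * 0)
    else lapply(p, walk)
  }
  list(state = walk(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      p <- p - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      list(p = p, s = s)
    } else {
      out <- Map(walk, p, g, s)
      list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s"))
    }
  }
  res <- walk(params, grads, opt$state)
  opt$state <- res$s
  list(params = res$p, opt = opt)
}

# Elementwise sum of two gradient trees (same shape).
grad_add <- function(a, b) {
  if (is.numeric(a)) a + b else Map(grad_add, a, b)
}

grad_scale <- function(a, s) {
  if (is.numeric(a)) a * s else lapply(a, grad_scale, s = s)
}
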