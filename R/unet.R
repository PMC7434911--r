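#' U-Net configuration
#'
#' Architecture of the single-channel denoising U-Net: an encoder of
#' `depth` levels (two 3x3 convolutions per level, each followed by batch
#' normalisation placed before the ReLU activation, then 2x2 max pooling), a
#' two-convolution bottleneck, and a mirrored decoder using 2x2 transposed
#' convolutions for upsampling with skip connections at matching resolutions.
#' Input and output are one channel.
#'
#' @param depth Number of encoder levels (default 4).
#' @param base_channels Channels of the first level, doubled per level
#'   (default 16).
#' @param kernel Convolution kernel side (default 3).
#' @return A `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 16L, kernel = 3L) {
  if (depth < 1L || base_channels < 1L || kernel %% 2L != 1L)
    mrd_error("invalid U-Net configuration", "mrd_parameter_error")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 kernel = as.integer(kernel),
                 in_channels = 1L, out_channels = 1L),
            class = "unet_config")
}

conv_block_init <- function(cin, cout, k) {
  list(W = he_init(k * k * cin, cout, fan_in = k * k * cin),
       b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       rm = numeric(cout), rv = rep(1, cout))
}

unet_init <- function(config, seed = NULL) {
  with_seed(seed, {
    k <- config$kernel
    ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
    cb <- config$base_channels * 2^config$depth
    enc <- vector("list", config$depth)
    cin <- config$in_channels
    for (l in seq_len(config$depth)) {
      enc[[l]] <- list(cb1 = conv_block_init(cin, ch[l], k),
                       cb2 = conv_block_init(ch[l], ch[l], k))
      cin <- ch[l]
    }
    bott <- list(cb1 = conv_block_init(ch[config$depth], cb, k),
                 cb2 = conv_block_init(cb, cb, k))
    dec <- vector("list", config$depth)
    up_in <- cb
    for (l in rev(seq_len(config$depth))) {
      dec[[l]] <- list(
        up = list(W = he_init(up_in, 4L * ch[l], fan_in = up_in),
                  b = numeric(ch[l])),
        cb1 = conv_block_init(2L * ch[l], ch[l], k),
        cb2 = conv_block_init(ch[l], ch[l], k))
      up_in <- ch[l]
    }
    final <- list(W = he_init(ch[1], config$out_channels, fan_in = ch[1]),
                  b = numeric(config$out_channels))
    list(enc = enc, bott = bott, dec = dec, final = final)
  })
}

conv_block_fwd <- function(xs, pw, k, training) {
  h <- conv_fwd(xs, pw$W, pw$b, k)
  bn <- bn_fwd(h, pw$gamma, pw$beta, pw$rm, pw$rv, training)
  y <- relu_fwd(bn$y)
  list(y = y, cache = list(x = xs, bn = bn$cache, y = y),
       rm = bn$rm, rv = bn$rv)
}

conv_block_bwd <- function(dys, cache, pw, k) {
  d1 <- relu_bwd(dys, cache$y)
  d2 <- bn_bwd(d1, cache$bn, pw$gamma)
  d3 <- conv_bwd(cache$x, d2$dx, pw$W, k)
  list(dx = d3$dx,
       grads = list(W = d3$dW, b = as.numeric(d3$db),
                    gamma = d2$dgamma, beta = d2$dbeta,
                    rm = 0 * pw$rm, rv = 0 * pw$rv))
}

unet_forward <- function(params, xs, config, training = FALSE) {
  k <- config$kernel
  depth <- config$depth
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  upd <- params
  h <- xs
  skips <- vector("list", depth)
  for (l in seq_len(depth)) {
    c1 <- conv_block_fwd(h, params$enc[[l]]$cb1, k, training)
    c2 <- conv_block_fwd(c1$y, params$enc[[l]]$cb2, k, training)
    skips[[l]] <- c2$y
    pool <- nn_pool_fwd(c2$y)
    cache$enc[[l]] <- list(cb1 = c1$cache, cb2 = c2$cache, idx = pool$idx,
                           hw = dim(c2$y[[1]])[1:2])
    upd$enc[[l]]$cb1[c("rm", "rv")] <- list(c1$rm, c1$rv)
    upd$enc[[l]]$cb2[c("rm", "rv")] <- list(c2$rm, c2$rv)
    h <- pool$out
  }
  b1 <- conv_block_fwd(h, params$bott$cb1, k, training)
  b2 <- conv_block_fwd(b1$y, params$bott$cb2, k, training)
  cache$bott <- list(cb1 = b1$cache, cb2 = b2$cache)
  upd$bott$cb1[c("rm", "rv")] <- list(b1$rm, b1$rv)
  upd$bott$cb2[c("rm", "rv")] <- list(b2$rm, b2$rv)
  h <- b2$y
  for (l in rev(seq_len(depth))) {
    pw <- params$dec[[l]]
    upin <- h
    h <- nn_upconv_fwd(h, pw$up$W, pw$up$b)
    hcat <- cat_channels(h, skips[[l]])
    c1 <- conv_block_fwd(hcat, pw$cb1, k, training)
    c2 <- conv_block_fwd(c1$y, pw$cb2, k, training)
    cache$dec[[l]] <- list(upin = upin, cup = dim(h[[1]])[3],
                           cb1 = c1$cache, cb2 = c2$cache)
    upd$dec[[l]]$cb1[c("rm", "rv")] <- list(c1$rm, c1$rv)
    upd$dec[[l]]$cb2[c("rm", "rv")] <- list(c2$rm, c2$rv)
    h <- c2$y
  }
  out <- lapply(h, function(x) {
    d <- dim(x)
    y <- matrix(x, ncol = d[3]) %*% params$final$W
    y <- sweep(y, 2, params$final$b, "+")
    array(y, c(d[1], d[2], ncol(params$final$W)))
  })
  cache$pre_final <- h
  list(out = out, cache = cache, params = upd)
}

unet_backward <- function(params, cache, douts, config) {
  k <- config$kernel
  depth <- config$depth
  grads <- params  # same shape, filled below
  h <- cache$pre_final
  dW <- 0; db <- 0
  dh <- vector("list", length(douts))
  for (n in seq_along(douts)) {
    d <- dim(h[[n]])
    dy <- matrix(douts[[n]], ncol = dim(douts[[n]])[3])
    x <- matrix(h[[n]], ncol = d[3])
    dW <- dW + crossprod(x, dy)
    db <- db + colSums(dy)
    dh[[n]] <- array(dy %*% t(params$final$W), d)
  }
  grads$final <- list(W = dW, b = as.numeric(db))
  dskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    cc <- cache$dec[[l]]
    b2 <- conv_block_bwd(dh, cc$cb2, params$dec[[l]]$cb2, k)
    b1 <- conv_block_bwd(b2$dx, cc$cb1, params$dec[[l]]$cb1, k)
    sp <- split_channels(b1$dx, cc$cup)
    dskips[[l]] <- sp[[2]]
    up <- nn_upconv_bwd(cc$upin, sp[[1]], params$dec[[l]]$up$W)
    grads$dec[[l]] <- list(up = list(W = up$dW, b = as.numeric(up$db)),
                           cb1 = b1$grads, cb2 = b2$grads)
    dh <- up$dx
  }
  b2 <- conv_block_bwd(dh, cache$bott$cb2, params$bott$cb2, k)
  b1 <- conv_block_bwd(b2$dx, cache$bott$cb1, params$bott$cb1, k)
  grads$bott <- list(cb1 = b1$grads, cb2 = b2$grads)
  dh <- b1$dx
  for (l in rev(seq_len(depth))) {
    cc <- cache$enc[[l]]
    dpool <- nn_pool_bwd(cc$idx, dh, cc$hw[1], cc$hw[2])
    dsum <- grad_add(dpool, dskips[[l]])
    b2 <- conv_block_bwd(dsum, cc$cb2, params$enc[[l]]$cb2, k)
    b1 <- conv_block_bwd(b2$dx, cc$cb1, params$enc[[l]]$cb1, k)
    grads$enc[[l]] <- list(cb1 = b1$grads, cb2 = b2$grads)
    dh <- b1$dx
  }
  grads
}
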