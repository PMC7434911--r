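#' CycleGAN configuration
#'
#' Unsupervised denoiser: two U-Net generators (`G_AB`: noisy domain A to
#' clean domain B, `G_BA`: the reverse) and two convolutional discriminators
#' trained adversarially with least-squares (MSE) GAN losses plus an L1
#' cycle-consistency loss weighted by `lambda`. The discriminator has five
#' convolution layers (4x4, stride 2, channel doubling) followed by a fully
#' connected (1x1 convolution) layer whose output is average-pooled to a
#' single scalar; every convolution except the first is followed by instance
#' normalisation, and every convolution by a leaky-ReLU (slope 0.2).
#'
#' @param generator A [unet_config()] for both generators (desk default:
#'   depth 2, base 8).
#' @param disc_channels First discriminator layer channels (doubled per
#'   layer, capped at 8x).
#' @param lambda Cyclic-loss weight (default 10); `lambda = 0` is allowed
#'   but warns (pure GAN, no cycle constraint).
#' @param epochs Training epochs (desk default 8; reference protocol 200).
#' @param learning_rate Adam learning rate (default 0.002).
#' @param seed Seed for initialisation and shuffling.
#' @return A `cyclegan_config`.
#' @export
cyclegan_config <- function(generator = unet_config(depth = 2L, base_channels = 8L),
                            disc_channels = 8L, lambda = 10, epochs = 8L,
                            learning_rate = 0.002, seed = 1L) {
  if (lambda < 0 || epochs < 1L || learning_rate <= 0)
    mrd_error("invalid CycleGAN configuration", "mrd_parameter_error")
  if (lambda == 0)
    mrd_warn("lambda = 0: no cycle-consistency constraint (pure GAN)",
             "mrd_config_warning")
  structure(list(generator = generator, disc_channels = as.integer(disc_channels),
                 lambda = lambda, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cyclegan_config")
}

#' Least-squares GAN loss terms
#'
#' For discriminator outputs on real and generated samples, returns the
#' generator term `mean((1 - D(fake))^2)` and the discriminator term
#' `mean((D(real) - 1)^2) + mean(D(fake)^2)`.
#'
#' @param disc_real,disc_fake Numeric vectors of discriminator scalar
#'   outputs.
#' @return List with `generator` and `discriminator` loss values.
#' @export
lsgan_losses <- function(disc_real, disc_fake) {
  if (!all(is.finite(disc_real)) || !all(is.finite(disc_fake)))
    mrd_error("discriminator outputs must be finite", "mrd_parameter_error")
  list(generator = mean((1 - disc_fake)^2),
       discriminator = mean((disc_real - 1)^2) + mean(disc_fake^2))
}

#' L1 cycle-consistency loss
#'
#' Mean absolute error of `G_BA(G_AB(x_A))` against `x_A` plus that of
#' `G_AB(G_BA(x_B))` against `x_B`.
#'
#' @param x_A,x_B Numeric matrices (one image per domain).
#' @param G_AB,G_BA Functions mapping a matrix to a matrix.
#' @return Non-negative scalar.
#' @export
cyclic_loss <- function(x_A, x_B, G_AB, G_BA) {
  ra <- G_BA(G_AB(x_A))
  rb <- G_AB(G_BA(x_B))
  if (!identical(dim(ra), dim(x_A)) || !identical(dim(rb), dim(x_B)))
    mrd_error("generator output shape mismatch", "mrd_shape_error")
  mean(abs(ra - x_A)) + mean(abs(rb - x_B))
}

# --- discriminator ----------------------------------------------------------

disc_init <- function(cin, base) {
  ch <- base * c(1L, 2L, 4L, 8L, 8L)
  layers <- vector("list", 5L)
  for (l in 1:5) {
    layers[[l]] <- list(W = he_init(16L * cin, ch[l], fan_in = 16L * cin),
                        b = numeric(ch[l]),
                        gamma = rep(1, ch[l]), beta = numeric(ch[l]))
    cin <- ch[l]
  }
  list(layers = layers,
       fc = list(W = he_init(ch[5], 1L, fan_in = ch[5]), b = 0))
}

disc_forward <- function(params, xs) {
  cache <- list(layers = vector("list", 5L))
  h <- xs
  for (l in 1:5) {
    pw <- params$layers[[l]]
    hin <- h
    h <- conv_fwd(h, pw$W, pw$b, k = 4L, stride = 2L, pad = 1L)
    inc <- NULL
    if (l > 1L) {
      r <- in_fwd(h, pw$gamma, pw$beta)
      inc <- r$cache
      h <- r$y
    }
    pre <- h
    h <- lrelu_fwd(h)
    cache$layers[[l]] <- list(x = hin, inc = inc, pre = pre)
  }
  # fully connected (1x1 conv) then global average pool to a scalar
  cache$pre_fc <- h
  scores <- vapply(h, function(x) {
    d <- dim(x)
    y <- matrix(x, ncol = d[3]) %*% params$fc$W + params$fc$b
    mean(y)
  }, numeric(1))
  list(scores = scores, cache = cache)
}

disc_backward <- function(params, cache, dscores) {
  h <- cache$pre_fc
  dW <- 0; db <- 0
  dh <- vector("list", length(h))
  for (n in seq_along(h)) {
    d <- dim(h[[n]])
    npx <- d[1] * d[2]
    x <- matrix(h[[n]], ncol = d[3])
    dy <- matrix(dscores[n] / npx, npx, 1L)
    dW <- dW + crossprod(x, dy)
    db <- db + sum(dy)
    dh[[n]] <- array(dy %*% t(params$fc$W), d)
  }
  grads <- params
  grads$fc <- list(W = dW, b = db)
  for (l in 5:1) {
    cc <- cache$layers[[l]]
    pw <- params$layers[[l]]
    dh <- lrelu_bwd(dh, cc$pre)
    if (l > 1L) {
      r <- in_bwd(dh, cc$inc, pw$gamma)
      dh <- r$dx
      dgamma <- r$dgamma; dbeta <- r$dbeta
    } else {
      dgamma <- 0 * pw$gamma; dbeta <- 0 * pw$beta
    }
    cb <- conv_bwd(cc$x, dh, pw$W, k = 4L, stride = 2L, pad = 1L)
    grads$layers[[l]] <- list(W = cb$dW, b = as.numeric(cb$db),
                              gamma = dgamma, beta = dbeta)
    dh <- cb$dx
  }
  list(dx = dh, grads = grads)
}

# --- training ---------------------------------------------------------------

#' Train the unsupervised CycleGAN denoiser
#'
#' Alternates one generator update and one discriminator update per step,
#' minimising the least-squares adversarial losses plus `lambda` times the
#' L1 cyclic loss. Per-epoch means of the loss components
#' (adversarial A->B, B->A, cyclic, and the decomposed total) are logged.
#'
#' @param data An `unpaired_dataset` from [make_unpaired_dataset()].
#' @param config A [cyclegan_config()].
#' @return A trained `cyclegan_model` holding `G_AB`, `G_BA`, `D_A`, `D_B`
#'   and the loss log.
#' @export
train_cyclegan <- function(data, config = cyclegan_config()) {
  stopifnot(inherits(data, "unpaired_dataset"), inherits(config, "cyclegan_config"))
  if (length(data$domain_A) < 1L || length(data$domain_B) < 1L)
    mrd_error("both domains must be non-empty", "mrd_parameter_error")
  gcfg <- config$generator
  A <- lapply(data$domain_A, function(im) {
    px <- as_pixel_matrix(im); st <- norm_stats(px); norm_apply(px, st)
  })
  B <- lapply(data$domain_B, function(im) {
    px <- as_pixel_matrix(im); st <- norm_stats(px); norm_apply(px, st)
  })
  if (any(dim(A[[1]]) %% 2^gcfg$depth != 0))
    mrd_error("image sides must be divisible by 2^depth", "mrd_shape_error")

  with_seed(config$seed, {
    G_AB <- unet_init(gcfg)
    G_BA <- unet_init(gcfg)
    D_A <- disc_init(1L, config$disc_channels)
    D_B <- disc_init(1L, config$disc_channels)
    opt <- list(gab = adam_init(G_AB), gba = adam_init(G_BA),
                da = adam_init(D_A), db = adam_init(D_B))
    lr <- config$learning_rate
    lam <- config$lambda
    log <- NULL

    steps <- max(length(A), length(B))
    for (epoch in seq_len(config$epochs)) {
      ia <- rep_len(sample.int(length(A)), steps)
      ib <- rep_len(sample.int(length(B)), steps)
      acc <- c(gan_ab = 0, gan_ba = 0, cyc = 0, d_a = 0, d_b = 0)
      for (s in seq_len(steps)) {
        a <- as_batch(list(A[[ia[s]]]))
        b <- as_batch(list(B[[ib[s]]]))

        # ---- generator update ----
        f_ab <- unet_forward(G_AB, a, gcfg, training = TRUE)   # fake B
        G_AB <- f_ab$params
        f_aba <- unet_forward(G_BA, f_ab$out, gcfg, training = TRUE)  # rec A
        G_BA <- f_aba$params
        f_ba <- unet_forward(G_BA, b, gcfg, training = TRUE)   # fake A
        G_BA <- f_ba$params
        f_bab <- unet_forward(G_AB, f_ba$out, gcfg, training = TRUE)  # rec B
        G_AB <- f_bab$params

        db_fake <- disc_forward(D_B, f_ab$out)
        da_fake <- disc_forward(D_A, f_ba$out)

        npx <- length(a[[1]])
        cyc_a <- mean(abs(f_aba$out[[1]] - a[[1]]))
        cyc_b <- mean(abs(f_bab$out[[1]] - b[[1]]))
        gan_ab <- (1 - db_fake$scores[1])^2
        gan_ba <- (1 - da_fake$scores[1])^2
        total <- gan_ab + gan_ba + lam * (cyc_a + cyc_b)
        if (!is.finite(total))
          mrd_error(sprintf("CycleGAN diverged (non-finite loss) at epoch %d", epoch),
                    "mrd_divergence_error")

        # gradients wrt cycle reconstructions
        d_rec_a <- list(sign(f_aba$out[[1]] - a[[1]]) * lam / npx)
        d_rec_b <- list(sign(f_bab$out[[1]] - b[[1]]) * lam / npx)
        # adversarial gradients through the discriminators (params fixed)
        d_fab_adv <- disc_backward(D_B, db_fake$cache,
                                   2 * (db_fake$scores - 1))$dx
        d_fba_adv <- disc_backward(D_A, da_fake$cache,
                                   2 * (da_fake$scores - 1))$dx

        # backprop cycles into the producing generators
        g_gba_1 <- unet_backward(G_BA, f_aba$cache, d_rec_a, gcfg)  # via rec A
        d_fab <- grad_add(attr_dx(G_BA, f_aba, d_rec_a, gcfg), d_fab_adv)
        g_gab_1 <- unet_backward(G_AB, f_ab$cache, d_fab, gcfg)

        g_gab_2 <- unet_backward(G_AB, f_bab$cache, d_rec_b, gcfg)  # via rec B
        d_fba <- grad_add(attr_dx(G_AB, f_bab, d_rec_b, gcfg), d_fba_adv)
        g_gba_2 <- unet_backward(G_BA, f_ba$cache, d_fba, gcfg)

        gab_grads <- grad_add(g_gab_1, g_gab_2)
        gba_grads <- grad_add(g_gba_1, g_gba_2)
        st <- adam_step(G_AB, gab_grads, opt$gab, lr)
        G_AB <- st$params; opt$gab <- st$opt
        st <- adam_step(G_BA, gba_grads, opt$gba, lr)
        G_BA <- st$params; opt$gba <- st$opt

        # ---- discriminator update (fakes detached) ----
        db_real <- disc_forward(D_B, b)
        db_fake2 <- disc_forward(D_B, f_ab$out)
        l_db <- lsgan_losses(db_real$scores, db_fake2$scores)$discriminator
        gr <- disc_backward(D_B, db_real$cache, 2 * (db_real$scores - 1))$grads
        gf <- disc_backward(D_B, db_fake2$cache, 2 * db_fake2$scores)$grads
        st <- adam_step(D_B, grad_add(gr, gf), opt$db, lr)
        D_B <- st$params; opt$db <- st$opt

        da_real <- disc_forward(D_A, a)
        da_fake2 <- disc_forward(D_A, f_ba$out)
        l_da <- lsgan_losses(da_real$scores, da_fake2$scores)$discriminator
        gr <- disc_backward(D_A, da_real$cache, 2 * (da_real$scores - 1))$grads
        gf <- disc_backward(D_A, da_fake2$cache, 2 * da_fake2$scores)$grads
        st <- adam_step(D_A, grad_add(gr, gf), opt$da, lr)
        D_A <- st$params; opt$da <- st$opt

        acc <- acc + c(gan_ab, gan_ba, cyc_a + cyc_b, l_da, l_db)
      }
      acc <- acc / steps
      log <- rbind(log, data.frame(
        epoch = epoch, gan_ab = acc[1], gan_ba = acc[2], cyclic = acc[3],
        total = acc[1] + acc[2] + lam * acc[3],
        disc_a = acc[4], disc_b = acc[5], row.names = NULL))
    }
    structure(list(G_AB = G_AB, G_BA = G_BA, D_A = D_A, D_B = D_B,
                   config = config, log = log, trained = TRUE,
                   norm = "per-image z-score"),
              class = c("cyclegan_model", "mrd_denoiser"))
  })
}

# Input gradient of a U-Net forward pass: same chain as unet_backward but
# returns d(loss)/d(input) instead of the parameter gradients.
attr_dx <- function(params, fw, douts, config) {
  k <- config$kernel
  depth <- config$depth
  cache <- fw$cache
  h <- cache$pre_final
  dh <- vector("list", length(douts))
  for (n in seq_along(douts)) {
    d <- dim(h[[n]])
    dy <- matrix(douts[[n]], ncol = dim(douts[[n]])[3])
    dh[[n]] <- array(dy %*% t(params$final$W), d)
  }
  dskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    cc <- cache$dec[[l]]
    b2 <- conv_block_bwd(dh, cc$cb2, params$dec[[l]]$cb2, k)
    b1 <- conv_block_bwd(b2$dx, cc$cb1, params$dec[[l]]$cb1, k)
    sp <- split_channels(b1$dx, cc$cup)
    dskips[[l]] <- sp[[2]]
    up <- nn_upconv_bwd(cc$upin, sp[[1]], params$dec[[l]]$up$W)
    dh <- up$dx
  }
  b2 <- conv_block_bwd(dh, cache$bott$cb2, params$bott$cb2, k)
  b1 <- conv_block_bwd(b2$dx, cache$bott$cb1, params$bott$cb1, k)
  dh <- b1$dx
  for (l in rev(seq_len(depth))) {
    cc <- cache$enc[[l]]
    dpool <- nn_pool_bwd(cc$idx, dh, cc$hw[1], cc$hw[2])
    dsum <- grad_add(dpool, dskips[[l]])
    b2 <- conv_block_bwd(dsum, cc$cb2, params$enc[[l]]$cb2, k)
    b1 <- conv_block_bwd(b2$dx, cc$cb1, params$enc[[l]]$cb1, k)
    dh <- b1$dx
  }
  dh
}

#' @export
print.cyclegan_model <- function(x, ...) {
  cat(sprintf("<cyclegan_model: U-Net generators depth %d, trained %d epochs, lambda %.3g>\n",
              x$config$generator$depth, nrow(x$log), x$config$lambda))
  invisible(x)
}

#' @export
summary.cyclegan_model <- function(object, ...) {
  print(object)
  cat(sprintf("  cyclic loss epoch 1: %.5g, final: %.5g\n",
              object$log$cyclic[1], object$log$cyclic[nrow(object$log)]))
  invisible(object)
}

#' @export
plot.cyclegan_model <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$cyclic, x$log$gan_ab, x$log$gan_ba),
                    type = "b", pch = 16, lty = 1,
                    xlab = "epoch", ylab = "loss",
                    main = "CycleGAN training", ...)
  graphics::legend("topright", c("cyclic", "GAN A->B", "GAN B->A"),
                   col = 1:3, pch = 16, bty = "n")
  invisible(x)
}

#' Translate an image between domains
#'
#' Applies a trained CycleGAN generator (`"AB"`: noisy to clean, `"BA"`: the
#' reverse) in inference mode; deterministic.
#'
#' @param model A trained `cyclegan_model`.
#' @param image A [gray_image()] or matrix.
#' @param direction `"AB"` or `"BA"`.
#' @return Translated [gray_image()].
#' @export
translate <- function(model, image, direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  if (!inherits(model, "cyclegan_model") || !isTRUE(model$trained))
    mrd_error("model must be a trained cyclegan_model", "mrd_state_error")
  px <- as_pixel_matrix(image)
  st <- norm_stats(px)
  x <- norm_apply(px, st)
  gcfg <- model$config$generator
  padded <- reflect_pad_multiple(x, 2^gcfg$depth)
  params <- if (direction == "AB") model$G_AB else model$G_BA
  fw <- unet_forward(params, as_batch(list(padded$x)), gcfg, training = FALSE)
  y <- fw$out[[1]][, , 1][seq_len(nrow(px)), seq_len(ncol(px))]
  reimage(if (inherits(image, "gray_image")) image else gray_image(px, check = FALSE),
          norm_invert(y, st))
}

#' @export
predict.cyclegan_model <- function(object, newdata, direction = "AB", ...)
  translate(object, newdata, direction)
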