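#' Training configuration for the self-supervised denoiser
#'
#' The reference protocol trains with 256 x 256 patches for 200 epochs at a
#' learning rate of 0.002; the desk-scale defaults (64 x 64 patches, 20
#' epochs) run the identical algorithm at a size suited to a single CPU.
#'
#' @param epochs Training epochs (desk default 20; reference protocol 200).
#' @param learning_rate Adam learning rate (default 0.002).
#' @param patch_size Side of the square training patches (desk default 64;
#'   reference protocol 256). Must not exceed the image side.
#' @param batch_size Minibatch size (default 4).
#' @param val_fraction Fraction of pairs held out for validation
#'   (default 1/6, mirroring the reference 1500/300 split).
#' @param seed Seed for initialisation, patch sampling and shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 20L, learning_rate = 0.002, patch_size = 64L,
                         batch_size = 4L, val_fraction = 1 / 6, seed = 1L) {
  if (epochs < 1L || learning_rate <= 0 || patch_size < 8L || batch_size < 1L ||
      val_fraction < 0 || val_fraction >= 1)
    mrd_error("invalid training configuration", "mrd_parameter_error")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) U-Net denoiser
#'
#' @param config A [unet_config()].
#' @param seed Seed for the He-normal weight initialisation.
#' @return An untrained `selfsup_denoiser` model object.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  structure(list(params = unet_init(config, seed = seed), config = config,
                 trained = FALSE, log = NULL, norm = "per-image z-score"),
            class = c("selfsup_denoiser", "mrd_denoiser"))
}

#' @export
print.selfsup_denoiser <- function(x, ...) {
  cat(sprintf("<selfsup_denoiser: U-Net depth %d, base %d channels, %s>\n",
              x$config$depth, x$config$base_channels,
              if (isTRUE(x$trained)) sprintf("trained %d epochs", nrow(x$log))
              else "untrained"))
  invisible(x)
}

# normalisation helpers: the network operates on per-image z-scores of the
# *input* image; the same statistics transform the target and invert the
# output, so the identity map is representable and inversion is consistent.
norm_stats <- function(px) {
  s <- stats::sd(px)
  list(m = mean(px), s = if (s > 0) s else 1)
}
norm_apply <- function(px, st) (px - st$m) / st$s
norm_invert <- function(px, st) px * st$s + st$m

as_batch <- function(mats) lapply(mats, function(m) array(m, c(dim(m), 1L)))

mse_batch <- function(ys, ts) {
  tot <- 0; n <- 0
  for (i in seq_along(ys)) {
    tot <- tot + sum((ys[[i]] - ts[[i]])^2)
    n <- n + length(ys[[i]])
  }
  tot / n
}

random_crop <- function(px, size) {
  nr <- nrow(px); nc <- ncol(px)
  if (size > nr || size > nc)
    mrd_error("patch size exceeds image side", "mrd_parameter_error")
  i <- if (nr == size) 1L else sample.int(nr - size + 1L, 1L)
  j <- if (nc == size) 1L else sample.int(nc - size + 1L, 1L)
  list(i = i, j = j)
}

#' Train the self-supervised U-Net denoiser
#'
#' Minimises the mean squared error between the network output on the
#' artificially corrupted input patch and the corresponding clean target
#' patch, with Adam. Inputs and targets are normalised with the input
#' image's per-image z-score statistics. Training is deterministic given the
#' configuration seed. The per-epoch train and validation losses are logged
#' (epoch 0 is the pre-training validation loss).
#'
#' @param pairs A `paired_dataset` from [make_paired_dataset()] (at least 2
#'   pairs).
#' @param unet A [unet_config()] or an untrained model from [build_unet()].
#' @param train A [train_config()].
#' @return A trained `selfsup_denoiser` with a `log` data frame of per-epoch
#'   losses.
#' @export
train_denoiser <- function(pairs, unet = unet_config(), train = train_config()) {
  stopifnot(inherits(pairs, "paired_dataset"), inherits(train, "train_config"))
  if (length(pairs$pairs) < 2L)
    mrd_error("need at least 2 pairs", "mrd_parameter_error")
  model <- if (inherits(unet, "unet_config"))
    build_unet(unet, seed = train$seed) else unet
  config <- model$config
  if (train$patch_size %% (2^config$depth) != 0L)
    mrd_error("patch size must be divisible by 2^depth", "mrd_shape_error")

  # pre-normalised training tensors
  prep <- lapply(pairs$pairs, function(p) {
    st <- norm_stats(as_pixel_matrix(p$noisy))
    list(x = norm_apply(as_pixel_matrix(p$noisy), st),
         t = norm_apply(as_pixel_matrix(p$clean), st))
  })

  with_seed(train$seed + 1L, {
    n <- length(prep)
    n_val <- max(1L, floor(train$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) < 1L)
      mrd_error("no training pairs left after validation split", "mrd_parameter_error")

    params <- model$params
    opt <- adam_init(params)
    ps <- train$patch_size

    val_loss <- function(params) {
      tot <- 0
      for (i in val_idx) {
        crop <- list(i = 1L, j = 1L)  # deterministic top-left validation crop
        x <- prep[[i]]$x[crop$i:(crop$i + ps - 1L), crop$j:(crop$j + ps - 1L)]
        t <- prep[[i]]$t[crop$i:(crop$i + ps - 1L), crop$j:(crop$j + ps - 1L)]
        fw <- unet_forward(params, as_batch(list(x)), config, training = FALSE)
        tot <- tot + mse_batch(fw$out, as_batch(list(t)))
      }
      tot / length(val_idx)
    }

    log <- data.frame(epoch = 0L, train_mse = NA_real_, val_mse = val_loss(params))
    for (epoch in seq_len(train$epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
      ep_loss <- 0; ep_n <- 0
      for (bt in batches) {
        xs <- list(); ts <- list()
        for (i in bt) {
          crop <- random_crop(prep[[i]]$x, ps)
          xs[[length(xs) + 1L]] <-
            prep[[i]]$x[crop$i:(crop$i + ps - 1L), crop$j:(crop$j + ps - 1L)]
          ts[[length(ts) + 1L]] <-
            prep[[i]]$t[crop$i:(crop$i + ps - 1L), crop$j:(crop$j + ps - 1L)]
        }
        xb <- as_batch(xs); tb <- as_batch(ts)
        fw <- unet_forward(params, xb, config, training = TRUE)
        params <- fw$params  # running BN statistics updated
        loss <- mse_batch(fw$out, tb)
        if (!is.finite(loss))
          mrd_error(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
                    "mrd_divergence_error")
        ep_loss <- ep_loss + loss * length(bt); ep_n <- ep_n + length(bt)
        ntot <- sum(vapply(fw$out, length, 1L))
        dout <- Map(function(y, t) 2 * (y - t) / ntot, fw$out, tb)
        grads <- unet_backward(params, fw$cache, dout, config)
        st <- adam_step(params, grads, opt, lr = train$learning_rate)
        params <- st$params; opt <- st$opt
      }
      log <- rbind(log, data.frame(epoch = epoch, train_mse = ep_loss / ep_n,
                                   val_mse = val_loss(params)))
    }
    model$params <- params
    model$trained <- TRUE
    model$log <- log
    model$train_config <- train
    model
  })
}

#' Apply a trained denoiser to an image
#'
#' Runs the trained U-Net in inference mode (stored batch-normalisation
#' statistics; fully deterministic). Images whose sides are not divisible by
#' `2^depth` are reflect-padded and cropped back.
#'
#' @param model A trained `selfsup_denoiser`.
#' @param image A [gray_image()] or numeric matrix.
#' @return The denoised [gray_image()], same size as the input.
#' @export
denoise <- function(model, image) {
  if (!inherits(model, "selfsup_denoiser"))
    mrd_error("`model` must be a selfsup_denoiser", "mrd_type_error")
  if (!isTRUE(model$trained))
    mrd_error("model is untrained", "mrd_state_error")
  px <- as_pixel_matrix(image)
  st <- norm_stats(px)
  x <- norm_apply(px, st)
  mult <- 2^model$config$depth
  padded <- reflect_pad_multiple(x, mult)
  fw <- unet_forward(model$params, as_batch(list(padded$x)), model$config,
                     training = FALSE)
  y <- fw$out[[1]][, , 1]
  y <- y[seq_len(nrow(px)), seq_len(ncol(px))]
  reimage(if (inherits(image, "gray_image")) image else gray_image(px, check = FALSE),
          norm_invert(y, st))
}

#' @export
predict.selfsup_denoiser <- function(object, newdata, ...) denoise(object, newdata)

reflect_pad_multiple <- function(x, mult) {
  nr <- nrow(x); nc <- ncol(x)
  pr <- (mult - nr %% mult) %% mult
  pc <- (mult - nc %% mult) %% mult
  if (pr > 0) x <- rbind(x, x[nr:(nr - pr + 1L), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, nc:(nc - pc + 1L), drop = FALSE])
  list(x = x, pr = pr, pc = pc)
}

#' Untrained forward pass (shape contract)
#'
#' Applies the (possibly untrained) network once; used to check the
#' output-shape contract and architecture arithmetic.
#' @param model A `selfsup_denoiser`.
#' @param image Matrix with sides divisible by `2^depth`.
#' @return Numeric matrix of the same size.
#' @keywords internal
#' @export
unet_apply_raw <- function(model, image) {
  px <- as_pixel_matrix(image)
  if (any(dim(px) %% (2^model$config$depth) != 0))
    mrd_error("input sides must be divisible by 2^depth", "mrd_shape_error")
  fw <- unet_forward(model$params, as_batch(list(px)), model$config,
                     training = FALSE)
  fw$out[[1]][, , 1]
}

#' @export
summary.selfsup_denoiser <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat(sprintf("  initial validation MSE: %.5g\n", object$log$val_mse[1]))
    cat(sprintf("  final   validation MSE: %.5g\n",
                object$log$val_mse[nrow(object$log)]))
  }
  invisible(object)
}

#' @export
plot.selfsup_denoiser <- function(x, ...) {
  if (is.null(x$log)) mrd_error("no training log to plot", "mrd_state_error")
  graphics::plot(x$log$epoch, x$log$val_mse, type = "b", pch = 16,
                 xlab = "epoch", ylab = "MSE",
                 main = "U-Net denoiser training", ...)
  graphics::lines(x$log$epoch[-1], x$log$train_mse[-1], type = "b", col = 2, pch = 1)
  graphics::legend("topright", c("validation", "train"), col = c(1, 2),
                   pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Save / load a model
#'
#' Serialises a trained model (any `mrdenoise` model object) to an RDS
#' container holding configuration, weights and training log; loading
#' restores it bit-exactly.
#'
#' @param model Model object.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
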