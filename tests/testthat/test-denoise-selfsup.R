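test_that("U-Net shape contract and architecture arithmetic hold", {
  m <- build_unet(unet_config(depth = 4, base_channels = 4), seed = 1)
  x <- matrix(rnorm(64 * 64), 64, 64)
  y <- unet_apply_raw(m, x)
  expect_identical(dim(y), dim(x))
  # bottleneck side = input / 2^depth
  fw <- mrdenoise:::unet_forward(m$params, mrdenoise:::as_batch(list(x)),
                                 m$config, training = FALSE)
  expect_identical(dim(fw$cache$bott$cb1$x[[1]])[1:2], c(4L, 4L))
  # indivisible sides are rejected by the raw applier
  expect_error(unet_apply_raw(m, matrix(0, 60, 60)), class = "mrd_shape_error")
  # seeded initialisation is reproducible
  m2 <- build_unet(unet_config(depth = 4, base_channels = 4), seed = 1)
  expect_identical(m$params, m2$params)
})

test_that("backpropagation matches finite differences throughout the network", {
  cfg <- unet_config(depth = 2, base_channels = 2)
  params <- mrdenoise:::unet_init(cfg, seed = 42)
  set.seed(1)
  x <- list(array(rnorm(16 * 16), c(16, 16, 1)))
  t <- list(array(rnorm(16 * 16), c(16, 16, 1)))
  loss_fn <- function(p) {
    fw <- mrdenoise:::unet_forward(p, x, cfg, training = TRUE)
    mean((fw$out[[1]] - t[[1]])^2)
  }
  fw <- mrdenoise:::unet_forward(params, x, cfg, training = TRUE)
  dout <- list(2 * (fw$out[[1]] - t[[1]]) / length(fw$out[[1]]))
  grads <- mrdenoise:::unet_backward(params, fw$cache, dout, cfg)
  eps <- 1e-6
  probes <- list(
    list(function(p) p$enc[[1]]$cb1$W, function(p, v) { p$enc[[1]]$cb1$W <- v; p }, 3L),
    list(function(p) p$enc[[2]]$cb2$gamma, function(p, v) { p$enc[[2]]$cb2$gamma <- v; p }, 1L),
    list(function(p) p$bott$cb1$W, function(p, v) { p$bott$cb1$W <- v; p }, 10L),
    list(function(p) p$dec[[2]]$up$W, function(p, v) { p$dec[[2]]$up$W <- v; p }, 5L),
    list(function(p) p$dec[[1]]$cb2$beta, function(p, v) { p$dec[[1]]$cb2$beta <- v; p }, 2L),
    list(function(p) p$final$W, function(p, v) { p$final$W <- v; p }, 1L))
  for (pr in probes) {
    get <- pr[[1]]; set <- pr[[2]]; idx <- pr[[3]]
    v <- get(params)
    vp <- v; vp[idx] <- vp[idx] + eps
    vm <- v; vm[idx] <- vm[idx] - eps
    num <- (loss_fn(set(params, vp)) - loss_fn(set(params, vm))) / (2 * eps)
    ana <- get(grads)[idx]
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("training on clean pairs approaches the identity and reduces loss", {
  pd <- make_paired_dataset(16, desk_spec(), noise_spec(sigma_frac_range = c(0, 0)),
                            seed = 2)
  m <- train_denoiser(pd, unet_config(depth = 2, base_channels = 8),
                      train_config(epochs = 100, patch_size = 64, batch_size = 4,
                                   learning_rate = 0.005, seed = 1))
  expect_lt(m$log$val_mse[nrow(m$log)], m$log$val_mse[1])
  ph <- generate_phantom(desk_spec(99))
  out <- denoise(m, ph$image)
  rel <- mean((out - ph$image)^2) / stats::var(as.vector(ph$image))
  expect_lt(rel, 0.01)
})

test_that("inference is deterministic and survives a serialisation round trip", {
  pd <- make_paired_dataset(4, desk_spec(), noise_spec(), seed = 3)
  m <- train_denoiser(pd, unet_config(depth = 2, base_channels = 4),
                      train_config(epochs = 2, patch_size = 64, batch_size = 2,
                                   seed = 1))
  ph <- generate_phantom(desk_spec(50))
  noisy <- add_noise(ph$image, noise_spec(seed = 5))
  y1 <- denoise(m, noisy)
  y2 <- denoise(m, noisy)
  expect_identical(unclass(y1), unclass(y2))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(unclass(denoise(m2, noisy)), unclass(y1))
  # odd-sized inputs are reflect-padded and cropped back
  odd <- noisy[1:63, 1:61]
  expect_identical(dim(denoise(m, gray_image(odd, check = FALSE))), dim(odd))
})

test_that("untrained models and bad configurations are rejected", {
  m <- build_unet(unet_config(depth = 2, base_channels = 4), seed = 1)
  expect_error(denoise(m, matrix(0, 64, 64)), class = "mrd_state_error")
  pd <- make_paired_dataset(2, desk_spec(), noise_spec(), seed = 1)
  expect_error(train_denoiser(pd, unet_config(depth = 3),
                              train_config(patch_size = 60)),
               class = "mrd_shape_error")
  expect_error(train_config(epochs = 0), class = "mrd_parameter_error")
})

test_that("training is deterministic given the seed", {
  pd <- make_paired_dataset(4, desk_spec(), noise_spec(), seed = 7)
  tc <- train_config(epochs = 2, patch_size = 64, batch_size = 2, seed = 11)
  m1 <- train_denoiser(pd, unet_config(depth = 2, base_channels = 4), tc)
  m2 <- train_denoiser(pd, unet_config(depth = 2, base_channels = 4), tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
})
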