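test_that("least-squares GAN loss terms follow the quadratic forms", {
  # fooled discriminator: generator term vanishes
  expect_equal(lsgan_losses(1, 1)$generator, 0)
  # perfect discriminator: discriminator term vanishes
  expect_equal(lsgan_losses(1, 0)$discriminator, 0)
  # undecided discriminator at 0.5: 0.25 + 0.25
  expect_equal(lsgan_losses(0.5, 0.5)$discriminator, 0.5)
  expect_equal(lsgan_losses(0.5, 0.5)$generator, 0.25)
  # batch expectations
  expect_equal(lsgan_losses(c(1, 0), c(0, 1))$discriminator,
               mean(c(0, 1)) + mean(c(0, 1)))
  expect_error(lsgan_losses(NaN, 0), class = "mrd_parameter_error")
})

test_that("cyclic loss measures round-trip L1 error", {
  x <- matrix(1, 32, 32)
  idf <- function(m) m
  expect_equal(cyclic_loss(x, x, idf, idf), 0)
  # inverse pair of shifts cancels
  expect_equal(cyclic_loss(x, x, function(m) m + 3, function(m) m - 3), 0)
  # identity one way, +1 shift the other: 1 per direction on unit images
  expect_equal(cyclic_loss(x, x, idf, function(m) m + 1), 2)
  expect_error(cyclic_loss(x, x, function(m) m[1:2, 1:2], idf),
               class = "mrd_shape_error")
})

test_that("discriminator gradients match finite differences", {
  set.seed(2)
  D <- mrdenoise:::disc_init(1L, 4L)
  x <- list(array(rnorm(64 * 64), c(64, 64, 1)))
  lossD <- function(p) (mrdenoise:::disc_forward(p, x)$scores[1] - 1)^2
  f <- mrdenoise:::disc_forward(D, x)
  bk <- mrdenoise:::disc_backward(D, f$cache, 2 * (f$scores - 1))
  eps <- 1e-6
  for (l in c(1L, 3L, 5L)) {
    p1 <- D; p1$layers[[l]]$W[2] <- p1$layers[[l]]$W[2] + eps
    p2 <- D; p2$layers[[l]]$W[2] <- p2$layers[[l]]$W[2] - eps
    num <- (lossD(p1) - lossD(p2)) / (2 * eps)
    expect_equal(bk$grads$layers[[l]]$W[2], num, tolerance = 1e-5)
  }
  # input gradient (the path that trains the generators)
  i <- 100L
  xp <- x; xp[[1]][i] <- xp[[1]][i] + eps
  xm <- x; xm[[1]][i] <- xm[[1]][i] - eps
  num <- ((mrdenoise:::disc_forward(D, xp)$scores[1] - 1)^2 -
            (mrdenoise:::disc_forward(D, xm)$scores[1] - 1)^2) / (2 * eps)
  expect_equal(bk$dx[[1]][i], num, tolerance = 1e-5)
})

test_that("lambda = 0 is allowed but warns", {
  expect_warning(cyclegan_config(lambda = 0), class = "mrd_config_warning")
})

test_that("a short training run is seeded, bookkeeps its losses, and translates deterministically", {
  ud <- make_unpaired_dataset(4, 4, desk_spec(), noise_spec(),
                              deform_magnitude = 2, seed = 4)
  cfg <- cyclegan_config(generator = unet_config(depth = 2, base_channels = 4),
                         disc_channels = 4, epochs = 2, seed = 1)
  cg1 <- train_cyclegan(ud, cfg)
  cg2 <- train_cyclegan(ud, cfg)
  expect_identical(cg1$log, cg2$log)
  expect_identical(cg1$G_AB, cg2$G_AB)
  # total decomposes as GAN(A->B) + GAN(B->A) + lambda * cyclic
  expect_equal(cg1$log$total,
               cg1$log$gan_ab + cg1$log$gan_ba + cfg$lambda * cg1$log$cyclic,
               tolerance = 1e-12)

  tr1 <- translate(cg1, ud$domain_A[[1]], "AB")
  tr2 <- translate(cg1, ud$domain_A[[1]], "AB")
  expect_identical(unclass(tr1), unclass(tr2))
  expect_identical(dim(tr1), dim(ud$domain_A[[1]]))

  # A->B then B->A round trip is bounded by the logged cyclic loss scale:
  # compare in the network's normalised units, on a training image
  px <- mrdenoise:::as_pixel_matrix(ud$domain_A[[1]])
  st <- mrdenoise:::norm_stats(px)
  xn <- mrdenoise:::norm_apply(px, st)
  gcfg <- cfg$generator
  fab <- mrdenoise:::unet_forward(cg1$G_AB, mrdenoise:::as_batch(list(xn)),
                                  gcfg, training = FALSE)
  faba <- mrdenoise:::unet_forward(cg1$G_BA, fab$out, gcfg, training = FALSE)
  l1 <- mean(abs(faba$out[[1]][, , 1] - xn))
  expect_lt(l1, 2 * cg1$log$cyclic[nrow(cg1$log)])

  # serialisation round trip
  path <- tempfile(fileext = ".rds")
  save_model(cg1, path)
  expect_identical(unclass(translate(load_model(path), ud$domain_A[[1]], "AB")),
                   unclass(tr1))
})
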