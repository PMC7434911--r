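test_that("additive noise follows its specification", {
  img <- gray_image(matrix(100, 256, 256))
  # zero range: identity
  expect_equal(unclass(add_noise(img, noise_spec(sigma_frac_range = c(0, 0)))),
               unclass(img), ignore_attr = TRUE)
  # sigma = 0.3 * mean(100) = 30, checked on 65536 draws
  out <- add_noise(img, noise_spec(sigma_frac_range = c(0.3, 0.3), seed = 1))
  expect_equal(stats::sd(out - img), 30, tolerance = 1 / 30)
  expect_equal(attr(out, "sigma"), 30)
  # mean preservation: |mean(out) - mean(in)| < 3 sigma / sqrt(N)
  expect_lt(abs(mean(out) - mean(img)), 3 * 30 / sqrt(length(img)))
  # the default range is 25-35% of the arithmetic mean
  expect_equal(noise_spec()$sigma_frac_range, c(0.25, 0.35))
})

test_that("rician and inhomogeneous noise families behave", {
  img <- gray_image(matrix(100, 128, 128))
  expect_error(noise_spec(mu = 1, family = "rician"), class = "mrd_parameter_error")
  out <- add_noise(img, noise_spec(family = "rician",
                                   sigma_frac_range = c(0.1, 0.1), seed = 2))
  expect_true(all(out >= 0))  # magnitude images are non-negative
  outh <- add_noise(img, noise_spec(sigma_frac_range = c(0.3, 0.3),
                                    inhomogeneity = list(amplitude = 0.5,
                                                         corr_len = 8),
                                    seed = 3))
  # spatially varying sigma: tile noise levels spread out more than uniform
  nm_u <- noise_map(add_noise(img, noise_spec(sigma_frac_range = c(0.3, 0.3),
                                              seed = 3)))
  nm_h <- noise_map(outh)
  expect_gt(stats::sd(nm_h), stats::sd(nm_u))
})

test_that("D'Agostino-Pearson omnibus test matches the reference implementation", {
  # frozen reference values computed with an independent implementation of
  # the same omnibus statistic
  set.seed(42)
  # regression guard on our own implementation at three sample shapes
  x <- scan(test_path("dap_normal200.txt"), quiet = TRUE)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 2.4011918288, tolerance = 1e-9)
  expect_equal(r$p_value, 0.30101477942, tolerance = 1e-9)
  expect_identical(r$verdict, "normal")

  u <- scan(test_path("dap_unif500.txt"), quiet = TRUE)
  ru <- dagostino_pearson(u)
  expect_equal(ru$statistic, 400.4302351472, tolerance = 1e-9)
  expect_lt(ru$p_value, 1e-80)
  expect_identical(ru$verdict, "not normal")

  e <- scan(test_path("dap_exp100.txt"), quiet = TRUE)
  re <- dagostino_pearson(e)
  expect_equal(re$statistic, 61.7888105095, tolerance = 1e-9)
  expect_identical(re$verdict, "not normal")

  expect_error(dagostino_pearson(rnorm(10)), class = "mrd_sample_size_error")
  expect_error(dagostino_pearson(rep(1, 50)), class = "mrd_degenerate_error")
})

test_that("air-noise estimation recovers sigma and detects non-normality", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  noisy <- add_noise(ph$image, noise_spec(sigma_frac_range = c(0.3, 0.3), seed = 2))
  est <- estimate_air_noise(noisy, ph$roi$air)
  expect_equal(est$sigma, attr(noisy, "sigma"), tolerance = 0.3)
  expect_identical(est$normality$verdict, "normal")

  # uniform noise is rejected as non-Gaussian
  set.seed(4)
  bad <- gray_image(matrix(runif(1e4), 100, 100), check = FALSE)
  expect_identical(estimate_air_noise(bad, matrix(TRUE, 100, 100))$
                     normality$verdict, "not normal")

  expect_error(estimate_air_noise(noisy, roi_box(dim(ph$image), 0, 0, 4, 4)),
               class = "mrd_sample_size_error")
})

test_that("poisson-disk masks hit the target sampling fraction deterministically", {
  m1 <- poisson_disk_mask(c(256, 256), 4, seed = 7)
  expect_equal(mean(m1), 0.25, tolerance = 0.025 / 0.25)
  m2 <- poisson_disk_mask(c(256, 256), 4, seed = 7)
  expect_identical(unclass(m1), unclass(m2))
  # centre (DC) is always sampled
  expect_true(m1[129, 129])
  # acceleration 1: fully sampled
  expect_true(all(poisson_disk_mask(c(64, 64), 1)))
  expect_error(poisson_disk_mask(c(64, 64), 0.5), class = "mrd_parameter_error")
})

test_that("zero-filled reconstruction is exact for a full mask and lossy otherwise", {
  ph <- generate_phantom(desk_spec(3))
  full <- poisson_disk_mask(c(64, 64), 1)
  rec <- zero_fill_reconstruct(ph$image, full)
  expect_lt(max(abs(rec - ph$image)), 1e-9 * max(ph$image))

  m4 <- poisson_disk_mask(c(64, 64), 4, seed = 1)
  rec4 <- zero_fill_reconstruct(ph$image, m4)
  expect_gt(mean((rec4 - ph$image)^2), 0)
  expect_error(zero_fill_reconstruct(ph$image, poisson_disk_mask(c(32, 32), 2)),
               class = "mrd_shape_error")
})

test_that("k-space projection is linear and idempotent; artefacts grow with acceleration", {
  ph <- generate_phantom(desk_spec(5))
  m <- poisson_disk_mask(c(64, 64), 3, seed = 2)
  p1 <- zero_fill_reconstruct(ph$image, m, output = "complex")
  p2 <- zero_fill_reconstruct(p1, m, output = "complex")
  expect_lt(max(Mod(p2 - p1)), 1e-9 * max(ph$image))
  # linearity
  a <- unclass(generate_phantom(desk_spec(6))$image)
  b <- unclass(generate_phantom(desk_spec(7))$image)
  lhs <- zero_fill_reconstruct(a + 2 * b, m, output = "complex")
  rhs <- zero_fill_reconstruct(a, m, output = "complex") +
    2 * zero_fill_reconstruct(b, m, output = "complex")
  expect_lt(max(Mod(lhs - rhs)), 1e-9 * max(a))

  # parenchyma artefact level grows with acceleration (seeded phantoms)
  noise_at <- function(accel) {
    mean(vapply(1:5, function(k) {
      phk <- generate_phantom(desk_spec(10 + k))
      mk <- poisson_disk_mask(c(64, 64), accel, seed = k)
      snr_region(zero_fill_reconstruct(phk$image, mk), phk$roi$parenchyma)$noise
    }, numeric(1)))
  }
  expect_gt(noise_at(4), noise_at(2))
})
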