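test_that("vessel-wall and region SNR follow their definitions", {
  img <- matrix(50, 64, 64)
  wall <- roi_box(c(64, 64), 0, 0, 4, 4)
  lumen <- roi_box(c(64, 64), 10, 10, 20, 20)
  img[wall] <- c(150, rep(100, 15))  # peak 150 in the wall
  set.seed(1)
  img[lumen] <- 30 + rnorm(400, sd = 10)
  r <- snr_vessel_wall(img, wall, lumen)
  expect_equal(r$signal, 150)
  expect_equal(r$noise, 10, tolerance = 0.1)
  expect_equal(r$snr, r$signal / r$noise)

  # known-moment region: N(100, 10^2) over 1e4 pixels -> SNR 10 +/- 0.2
  set.seed(2)
  big <- matrix(rnorm(1e4, 100, 10), 100, 100)
  rr <- snr_region(big, matrix(TRUE, 100, 100))
  expect_equal(rr$snr, 10, tolerance = 0.02)

  # degenerate ROIs are explicit errors, never Inf
  expect_error(snr_region(matrix(50, 64, 64), lumen),
               class = "mrd_undefined_snr_error")
  expect_error(snr_vessel_wall(matrix(7, 64, 64), wall, lumen),
               class = "mrd_undefined_snr_error")
})

test_that("adding zero-mean noise lowers region SNR in expectation", {
  base <- matrix(100, 64, 64)
  roi <- roi_box(c(64, 64), 8, 8, 40, 40)
  set.seed(3)
  base[roi] <- 100 + rnorm(1600, sd = 5)
  drops <- vapply(1:50, function(k) {
    noisy <- add_noise(gray_image(base), noise_spec(sigma_frac_range = c(0.2, 0.2),
                                                    seed = k))
    snr_region(noisy, roi)$snr - snr_region(base, roi)$snr
  }, numeric(1))
  expect_lt(mean(drops), 0)
})

test_that("SNR metrics are translation-covariant", {
  ph <- generate_phantom(desk_spec(4))
  noisy <- add_noise(ph$image, noise_spec(seed = 2))
  shifted <- gray_image(unclass(noisy) + 17, check = FALSE)
  r0 <- snr_region(noisy, ph$roi$parenchyma)
  r1 <- snr_region(shifted, ph$roi$parenchyma)
  expect_equal(r1$signal, r0$signal + 17)
  expect_equal(r1$noise, r0$noise)
  w0 <- snr_vessel_wall(noisy, ph$roi$vessel_wall, ph$roi$lumen)
  w1 <- snr_vessel_wall(shifted, ph$roi$vessel_wall, ph$roi$lumen)
  expect_equal(w1$noise, w0$noise)
})

test_that("noise maps are zero for constant images, local, and calibrated", {
  expect_true(all(noise_map(matrix(5, 50, 50)) == 0))
  # left constant, right noisy
  img <- matrix(0, 50, 50)
  set.seed(4)
  img[, 26:50] <- rnorm(50 * 25)
  nm <- noise_map(img)
  expect_true(all(nm[, 1:5] == 0))
  expect_true(all(nm[, 6:10] > 0))
  # mean tile sd matches the c4-corrected expectation for i.i.d. noise
  set.seed(5)
  big <- matrix(rnorm(500 * 500, sd = 3), 500, 500)
  n <- 25
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expect_equal(mean(noise_map(big)), 3 * c4, tolerance = 0.05)
  # and matches the global sd within 5%
  expect_equal(mean(noise_map(big)), stats::sd(big), tolerance = 0.05)
  expect_error(noise_map(img, window = 4), class = "mrd_parameter_error")
})

test_that("BRISQUE features are 36-dimensional, deterministic, and Gaussian-calibrated", {
  set.seed(6)
  g <- matrix(rnorm(1000 * 1000), 1000, 1000)
  f <- brisque_features(g)
  expect_length(f, 36)
  expect_true(all(is.finite(f)))
  # pure Gaussian noise: normalising by the locally estimated sigma clips
  # the tails, so the MSCN of i.i.d. noise is sub-Gaussian; the fitted GGD
  # shape sits near 2.9 (cross-checked against an independent
  # implementation of the same 7x7 / sigma 7/6 / C = 1 definition)
  expect_gt(f[["s1_mscn_shape"]], 2.7)
  expect_lt(f[["s1_mscn_shape"]], 3.2)
  f2 <- brisque_features(g)
  expect_identical(f, f2)
  expect_error(brisque_features(matrix(1, 64, 64)), class = "mrd_degenerate_error")
  expect_error(brisque_features(matrix(0, 16, 16)), class = "mrd_shape_error")
})

test_that("the fallback scorer ranks noisy above clean and stays in [0, 100]", {
  cleans <- lapply(1:5, function(k) generate_phantom(desk_spec(k))$image)
  scorer <- fit_brisque_scorer(cleans)
  s_clean <- brisque_score(cleans[[1]], scorer)
  noisy <- add_noise(cleans[[1]], noise_spec(sigma_frac_range = c(0.3, 0.3),
                                             seed = 1))
  s_noisy <- brisque_score(noisy, scorer)
  expect_gt(s_noisy, s_clean)
  expect_gte(s_clean, 0)
  expect_lte(s_noisy, 100)
  expect_error(brisque_score(cleans[[1]]), class = "mrd_configuration_error")
})

test_that("paired t and KS tests behave on degenerate and calibrated input", {
  x <- c(1, 2, 3, 4, 5)
  r <- paired_t_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # constant non-zero difference with some spread: strongly significant
  set.seed(7)
  a <- rnorm(30)
  r2 <- paired_t_test(a + 1 + rnorm(30, sd = 0.1), a)
  expect_lt(r2$p_value, 0.05)
  # all differences identical and non-zero: undefined variance is signalled
  expect_error(paired_t_test(x + 1, x), class = "mrd_degenerate_error")

  # KS type-I calibration: normal samples rarely rejected
  ok <- vapply(1:100, function(k) {
    set.seed(k)
    ks_normality(rnorm(500))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("quality_report aggregates all regional metrics", {
  ph <- generate_phantom(desk_spec(8))
  noisy <- add_noise(ph$image, noise_spec(seed = 3))
  q <- quality_report(noisy, ph$roi)
  expect_named(q[c("vessel_wall", "csf", "parenchyma")],
               c("vessel_wall", "csf", "parenchyma"))
  expect_s3_class(q$noise_map, "noise_map")
  expect_gt(q$parenchyma$noise, snr_region(ph$image, ph$roi$parenchyma)$noise)
})
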