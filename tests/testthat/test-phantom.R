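test_that("phantom generation is seeded-deterministic and geometrically consistent", {
  ph1 <- generate_phantom(phantom_spec(seed = 7))
  ph2 <- generate_phantom(phantom_spec(seed = 7))
  expect_identical(unclass(ph1$image), unclass(ph2$image))

  # ROI classes exist, are disjoint where required, air is dark
  expect_true(all(c("vessel_wall", "lumen", "csf", "parenchyma", "air") %in%
                    names(ph1$roi)))
  expect_false(any(ph1$roi$lumen & ph1$roi$vessel_wall))
  expect_lt(mean(ph1$image[ph1$roi$air]),
            0.02 * mean(ph1$image[ph1$roi$parenchyma]))

  # PD-like intensity ordering on region means
  m <- vapply(ph1$roi[c("air", "lumen", "parenchyma", "vessel_wall")],
              function(r) mean(ph1$image[r]), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("intensity ordering holds across many seeds and sizes", {
  for (seed in c(2, 11, 23)) {
    for (sp in list(phantom_spec(seed = seed), desk_spec(seed))) {
      ph <- generate_phantom(sp)
      m <- vapply(ph$roi[c("air", "lumen", "parenchyma", "vessel_wall")],
                  function(r) mean(ph$image[r]), numeric(1))
      expect_true(all(diff(m) > 0))
    }
  }
})

test_that("zero texture amplitude yields constant parenchyma", {
  ph <- generate_phantom(phantom_spec(seed = 3, texture_amplitude = 0))
  expect_equal(stats::var(ph$image[ph$roi$parenchyma]), 0)
})

test_that("lumen mask splits into n_vessels connected components", {
  ph <- generate_phantom(phantom_spec(seed = 5, n_vessels = 3))
  m <- matrix(0L, nrow(ph$image), ncol(ph$image))
  m[ph$roi$lumen] <- 1L
  expect_equal(max(mrdenoise:::label8(m)), 3L)
})

test_that("geometry errors are signalled when vessels cannot be placed", {
  expect_error(generate_phantom(phantom_spec(size = 64, n_vessels = 30,
                                             vessel_radii = c(8, 12))),
               class = "mrd_geometry_error")
})

test_that("deformation is an identity at magnitude 0 and seeded otherwise", {
  ph <- generate_phantom(desk_spec(2))
  expect_identical(deform(ph$image, 0), ph$image)
  d1 <- deform(ph$image, 2, seed = 9)
  d2 <- deform(ph$image, 2, seed = 9)
  expect_identical(unclass(d1), unclass(d2))
  expect_error(deform(ph$image, -1), class = "mrd_parameter_error")
})

test_that("deformation moves structure but preserves global intensity", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  d <- deform(ph$image, 2, seed = 1)
  expect_gt(mean((d - ph$image)^2), 0)
  expect_lt(abs(mean(d) - mean(ph$image)) / mean(ph$image), 0.01)
})

test_that("paired datasets are aligned, seeded, and unbiased", {
  pd <- make_paired_dataset(5, desk_spec(), noise_spec(), seed = 3)
  expect_length(pd$pairs, 5)
  for (p in pd$pairs)
    expect_identical(dim(p$clean), dim(p$noisy))

  # zero noise: corrupted equals clean
  pd0 <- make_paired_dataset(2, desk_spec(), noise_spec(sigma_frac_range = c(0, 0)),
                             seed = 3)
  expect_equal(unclass(pd0$pairs[[1]]$noisy), unclass(pd0$pairs[[1]]$clean),
               ignore_attr = TRUE)

  # E[corrupted | clean] = clean over >= 1e4 pixels, within 1% of
  # parenchyma mean
  pd1 <- make_paired_dataset(3, desk_spec(), noise_spec(), seed = 8)
  resid <- unlist(lapply(pd1$pairs, function(p) as.vector(p$noisy - p$clean)))
  expect_gt(length(resid), 1e4)
  pmean <- mean(pd1$pairs[[1]]$clean[pd1$pairs[[1]]$roi$parenchyma])
  expect_lt(abs(mean(resid)), 0.01 * pmean)
})

test_that("noise sigma fraction matches its specification over many pairs", {
  pd <- make_paired_dataset(100, desk_spec(), noise_spec(sigma_frac_range = c(0.3, 0.3)),
                            seed = 5)
  fr <- vapply(pd$pairs, function(p)
    stats::sd(p$noisy - p$clean) / mean(p$clean), numeric(1))
  expect_equal(mean(fr), 0.30, tolerance = 0.01 / 0.30)
})

test_that("unpaired datasets keep the domains misaligned and asymmetric in noise", {
  ud <- make_unpaired_dataset(4, 4, desk_spec(), noise_spec(),
                              deform_magnitude = 2, seed = 6)
  expect_length(ud$domain_A, 4)
  expect_length(ud$domain_B, 4)

  # independent draws differ even with no deformation and no noise
  ud0 <- make_unpaired_dataset(2, 2, desk_spec(),
                               noise_spec(sigma_frac_range = c(0, 0)),
                               deform_magnitude = 0, seed = 6)
  expect_gt(mean((ud0$domain_A[[1]] - ud0$domain_B[[1]])^2), 0)

  # domain A is much noisier than domain B in parenchyma
  nA <- mean(vapply(seq_along(ud$domain_A), function(k)
    snr_region(ud$domain_A[[k]], ud$roi_A[[k]]$parenchyma)$noise, numeric(1)))
  nB <- mean(vapply(seq_along(ud$domain_B), function(k)
    snr_region(ud$domain_B[[k]], ud$roi_B[[k]]$parenchyma)$noise, numeric(1)))
  expect_gt(nA, 2 * nB)
})
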