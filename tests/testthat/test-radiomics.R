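test_that("discretisation partitions the ROI range", {
  img <- matrix(c(0, 1, 2, 3), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  expect_equal(sort(unique(as.vector(discretise(img, roi, 4)))), 1:4)
  expect_true(all(discretise(img, roi, 1) == 1))
  # uniform values fill bins evenly
  set.seed(1)
  big <- matrix(runif(1e4), 100, 100)
  lab <- discretise(big, matrix(TRUE, 100, 100), 8)
  freq <- tabulate(lab, 8) / 1e4
  expect_true(all(abs(freq - 1 / 8) < 0.02))
  expect_error(discretise(matrix(1, 4, 4), matrix(TRUE, 4, 4), 4),
               class = "mrd_degenerate_error")
})

test_that("first-order features match hand computations", {
  expect_error(first_order_features(matrix(1:4, 2, 2), matrix(TRUE, 2, 2)),
               class = "mrd_roi_error")

  img <- matrix(rep(c(1, 2, 3, 4), 4), 4, 4)
  roi <- matrix(TRUE, 4, 4)
  f <- first_order_features(img, roi, bins = 4)
  expect_length(f, 18)
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_Range"]), 3)
  expect_equal(unname(f["firstorder_Energy"]), 4 * (1 + 4 + 9 + 16))
  expect_equal(unname(f["firstorder_Uniformity"]), 4 * 0.25^2)
  expect_equal(unname(f["firstorder_Skewness"]), 0, tolerance = 1e-12)

  cst <- suppressWarnings(first_order_features(matrix(5, 4, 4), roi, bins = 4))
  expect_equal(unname(cst["firstorder_Mean"]), 5)
  expect_equal(unname(cst["firstorder_Variance"]), 0)
  expect_equal(unname(cst["firstorder_Range"]), 0)
  expect_equal(unname(cst["firstorder_Uniformity"]), 1)
})

test_that("GLCM matrices match brute-force pair enumeration", {
  lab <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  # angle 0 (horizontal offset): (1,1) and (2,2) pairs, twice each after
  # symmetrisation
  P <- mrdenoise:::glcm_matrix(lab, 0L, 1L, 2L)
  expect_equal(P[1, 1], 2)
  expect_equal(P[2, 2], 2)
  expect_equal(P[1, 2] + P[2, 1], 0)
  # probability matrix sums to 1
  expect_equal(sum(P / sum(P)), 1)

  set.seed(42)
  for (rep in 1:100) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    G <- sample(2:4, 1)
    lab <- matrix(sample.int(G, nr * nc, replace = TRUE), nr, nc)
    if (runif(1) < 0.3) lab[sample(length(lab), 1)] <- NA  # ragged ROI
    for (o in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))) {
      expect_identical(mrdenoise:::glcm_matrix(lab, o[1], o[2], G),
                       oracle_glcm_counts(lab, o[1], o[2], G))
    }
  }
})

test_that("GLRLM matrices match brute-force run enumeration", {
  # constant 4x4 grid: one run of length 4 per row in the horizontal direction
  lab <- matrix(1L, 4, 4)
  rr <- mrdenoise:::glrlm_runs(lab)
  Ph <- mrdenoise:::glrlm_matrix_dir(rr$lines[rr$dir == 1], 1L)
  expect_equal(Ph[1, 4], 4)
  expect_equal(sum(Ph), 4)

  set.seed(43)
  dirs <- c(h = 1L, v = 2L, d2 = 3L, d1 = 4L)  # split order: anti-diag, diag
  for (rep in 1:100) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    G <- sample(2:4, 1)
    lab <- matrix(sample.int(G, nr * nc, replace = TRUE), nr, nc)
    if (runif(1) < 0.3) lab[sample(length(lab), 1)] <- NA
    rr <- mrdenoise:::glrlm_runs(lab)
    for (d in names(dirs)) {
      got <- mrdenoise:::glrlm_matrix_dir(rr$lines[rr$dir == dirs[[d]]], G)
      want <- oracle_glrlm(lab, d, G)
      # pad to common width before comparing
      w <- max(ncol(got), ncol(want))
      pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
      expect_equal(pad(got), pad(want))
    }
  }
})

test_that("texture families produce their canonical feature counts", {
  set.seed(2)
  img <- matrix(runif(400), 20, 20)
  roi <- matrix(TRUE, 20, 20)
  lab <- discretise(img, roi, 8)
  expect_length(texture_features(lab, "glcm"), 24)
  expect_length(texture_features(lab, "glrlm"), 16)
  expect_length(texture_features(lab, "glszm"), 16)
  expect_length(texture_features(lab, "ngtdm"), 5)
  expect_length(texture_features(lab, "gldm"), 14)
  # 75 texture features in total
  tot <- sum(vapply(c("glcm", "glrlm", "glszm", "ngtdm", "gldm"),
                    function(f) length(texture_features(lab, f)), integer(1)))
  expect_equal(tot, 75L)
  # single grey level: degenerate features become 0 with a warning
  expect_warning(texture_features(matrix(1L, 5, 5), "glcm"),
                 class = "mrd_degenerate_warning")
})

test_that("texture features are invariant to intensity shifts", {
  set.seed(3)
  img <- matrix(runif(256), 16, 16)
  roi <- matrix(TRUE, 16, 16)
  l1 <- discretise(img, roi, 8)
  l2 <- discretise(img + 100, roi, 8)
  expect_identical(l1, l2)
  expect_equal(texture_features(l1, "glcm"), texture_features(l2, "glcm"))
})

test_that("Haar sub-bands conserve energy and localise impulses", {
  set.seed(4)
  img <- matrix(rnorm(64 * 64), 64, 64)
  b <- wavelet_subbands(img)
  expect_named(b, c("LL", "LH", "HL", "HH"))
  expect_identical(dim(b$LL), c(32L, 32L))
  expect_equal(sum(vapply(b, function(m) sum(m^2), numeric(1))),
               sum(img^2), tolerance = 1e-8)
  # constant image: all detail bands vanish
  bc <- wavelet_subbands(matrix(3, 16, 16))
  expect_true(all(bc$LH == 0) && all(bc$HL == 0) && all(bc$HH == 0))
  # aligned impulse: exactly one non-zero coefficient per band
  imp <- matrix(0, 16, 16); imp[5, 7] <- 1
  bi <- wavelet_subbands(imp)
  for (band in bi) expect_equal(sum(band != 0), 1)
  expect_error(wavelet_subbands(matrix(0, 15, 16)), class = "mrd_shape_error")
})

test_that("the feature table has 465 stable columns and deterministic rows", {
  ph <- generate_phantom(desk_spec(5))
  noisy <- add_noise(ph$image, noise_spec(seed = 1))
  box <- roi_box(dim(ph$image), 20, 20, 16, 16)
  tab <- extract_feature_table(list(a = ph$image, b = noisy, a2 = ph$image),
                               box, radiomics_config(bins = 16))
  expect_equal(ncol(tab), 465L)
  expect_equal(nrow(tab), 3L)
  expect_true(all(is.finite(as.matrix(tab))))
  # duplicate image -> identical feature rows
  expect_equal(unlist(tab["a", ]), unlist(tab["a2", ]))
  # class partition covers all columns
  cls <- mrdenoise:::feature_class(colnames(tab))
  expect_equal(sum(cls == "first_order"), 18L)
  expect_equal(sum(cls == "texture"), 75L)
  expect_equal(sum(cls == "wavelet"), 372L)
})

test_that("Lin's CCC equals the direct moment formula and its symmetries", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 2.1, 2.9, 4.2)
  expect_equal(lin_ccc(x, y), oracle_ccc(x, y), tolerance = 1e-12)
  expect_equal(lin_ccc(x, x), 1)
  z <- c(-2, 0, 2)
  expect_equal(lin_ccc(z, -z), -1)
  expect_equal(lin_ccc(x, y), lin_ccc(y, x))
  # |CCC| <= |Pearson r|
  set.seed(5)
  for (k in 1:20) {
    a <- rnorm(10); b <- rnorm(10) + 0.5 * a
    expect_lte(abs(lin_ccc(a, b)), abs(stats::cor(a, b)) + 1e-12)
  }
  # sample-moment variant converges to the population one
  set.seed(6)
  a <- rnorm(5000); b <- a + rnorm(5000, sd = 0.3)
  expect_equal(lin_ccc(a, b), lin_ccc(a, b, type = "sample"), tolerance = 1e-3)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 1, 1)), class = "mrd_degenerate_error")
})

test_that("reproducibility reports flag identical tables and bury noisy ones", {
  ph <- lapply(1:4, function(k) generate_phantom(desk_spec(k))$image)
  box <- roi_box(c(64, 64), 20, 20, 16, 16)
  tab <- extract_feature_table(setNames(ph, paste0("i", 1:4)), box,
                               radiomics_config(bins = 16))
  same <- reproducibility_report(tab, tab)
  expect_true(all(same$per_feature$ccc[!is.na(same$per_feature$ccc)] == 1))
  expect_true(all(same$per_feature$reproducible |
                    is.na(same$per_feature$ccc)))

  # large independent noise destroys concordance
  set.seed(7)
  noisy_tab <- tab + matrix(rnorm(length(unlist(tab)),
                                  sd = 1e3 * (abs(as.matrix(tab)) + 1)),
                            nrow(tab))
  rep2 <- reproducibility_report(tab, noisy_tab)
  expect_lt(mean(rep2$per_feature$ccc, na.rm = TRUE), 0.2)
  expect_lt(mean(rep2$per_feature$reproducible), 0.05)
  expect_error(reproducibility_report(tab, tab[, 1:10]),
               class = "mrd_parameter_error")
})
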