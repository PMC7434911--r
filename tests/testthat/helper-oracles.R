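# Independent brute-force oracles and shared fixtures for the test suite.

# Desk-scale phantom: small enough for fast tests, same structure as the
# full-size phantom.
desk_spec <- function(seed = 1L) {
  phantom_spec(size = 64L, n_vessels = 2L, vessel_radii = c(4, 7),
               n_csf = 1L, csf_radii = c(4, 6), seed = seed)
}

desk_experiment_config <- function(seed = 1L, ...) {
  experiment_config(
    phantom = desk_spec(),
    unet = unet_config(depth = 3L, base_channels = 8L),
    train = train_config(epochs = 20L, patch_size = 64L, batch_size = 4L),
    cyclegan = cyclegan_config(lambda = 2, epochs = 30L),
    n_train = 200L, n_test = 20L, n_unpaired_A = 20L, n_unpaired_B = 20L,
    seed = seed, ...)
}

# Tiny configuration used for contract/determinism checks only.
mini_experiment_config <- function(seed = 1L) {
  experiment_config(
    phantom = desk_spec(),
    unet = unet_config(depth = 2L, base_channels = 4L),
    train = train_config(epochs = 2L, patch_size = 64L, batch_size = 4L),
    cyclegan = cyclegan_config(
      generator = unet_config(depth = 2L, base_channels = 4L),
      disc_channels = 4L, epochs = 2L),
    radiomics = radiomics_config(bins = 8L),
    n_train = 6L, n_test = 3L, n_unpaired_A = 4L, n_unpaired_B = 4L,
    radiomics_box = 10L, n_brisque_corpus = 3L, seed = seed)
}

# Brute-force symmetric co-occurrence counts for one offset: enumerate every
# pixel pair explicitly.
oracle_glcm_counts <- function(lab, dr, dc, G) {
  P <- matrix(0, G, G)
  for (i in seq_len(nrow(lab))) {
    for (j in seq_len(ncol(lab))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 < 1 || i2 > nrow(lab) || j2 < 1 || j2 > ncol(lab)) next
      a <- lab[i, j]; b <- lab[i2, j2]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P
}

# Brute-force run-length matrix for one direction: walk every maximal run.
oracle_glrlm <- function(lab, dir, G) {
  nr <- nrow(lab); nc <- ncol(lab)
  step <- switch(dir, h = c(0, 1), v = c(1, 0), d1 = c(1, 1), d2 = c(1, -1))
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    pi <- i - step[1]; pj <- j - step[2]
    inside <- pi >= 1 && pi <= nr && pj >= 1 && pj <= nc
    if (!inside) starts[[length(starts) + 1L]] <- c(i, j)
  }
  runs <- list()
  for (s in starts) {
    i <- s[1]; j <- s[2]
    cur <- NA; len <- 0
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      v <- lab[i, j]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      i <- i + step[1]; j <- j + step[2]
    }
    if (!is.na(cur) && len > 0) runs[[length(runs) + 1L]] <- c(cur, len)
  }
  if (!length(runs)) return(matrix(0, G, 1))
  Rmax <- max(vapply(runs, `[`, numeric(1), 2))
  P <- matrix(0, G, Rmax)
  for (r in runs) P[r[1], r[2]] <- P[r[1], r[2]] + 1
  P
}

# Direct evaluation of the concordance moment formula with explicit sums.
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  2 * cxy / (vx + vy + (mx - my)^2)
}

# Cached heavyweight artefacts shared between acceptance checks.
.mrd_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .mrd_cache)) {
    assign(key, force(expr), envir = .mrd_cache)
  }
  get(key, envir = .mrd_cache)
}

get_desk_summary <- function() {
  cached("desk_summary",
         suppressWarnings(run_experiment(desk_experiment_config(seed = 1L),
                                         verbose = FALSE)))
}

get_mini_summary <- function() {
  cached("mini_summary",
         suppressWarnings(run_experiment(mini_experiment_config(seed = 1L),
                                         verbose = FALSE)))
}
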