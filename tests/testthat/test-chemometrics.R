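pretreated_samples <- function(n = 4L, replicates = 2L, seed = 1L,
                               classes = 1:4) {
  cfg <- tiny_config(n = n, replicates = replicates, seed = seed,
                     classes = classes)
  ds <- generate_dataset(cfg)
  boneraman:::sample_mean_spectra(ds$spectra)
}

test_that("the spectral matrix has one row per sample and guards provenance", {
  sm <- pretreated_samples(5)
  m <- build_spectral_matrix(sm, "V")
  expect_equal(nrow(m$X), 20)
  expect_true(all(m$wavenumbers >= 1550 & m$wavenumbers <= 1730))
  expect_equal(length(m$sample_ids), 20)

  expect_error(build_spectral_matrix(sm, c(3000, 3400)), "range error")

  raw <- generate_dataset(tiny_config(n = 2))$spectra
  expect_error(build_spectral_matrix(raw), "pretreatment")

  mixed <- sm
  mixed[[1]] <- pretreat(mean_spectrum(list(raw[[1]], raw[[2]])),
                         pretreatment_record(sg_window = 7))
  expect_error(build_spectral_matrix(mixed), "different pretreatment")

  ## duplicated sample -> identical rows
  m2 <- build_spectral_matrix(c(sm[1], sm[1], sm[-1]), "V")
  expect_equal(m2$X[1, ], m2$X[2, ])
})

test_that("PCA matches a brute-force eigendecomposition on small matrices", {
  set.seed(31)
  for (i in 1:5) {
    X <- matrix(rnorm(15 * 12), 15, 12) %*% diag(runif(12, 0.1, 3))
    fit <- fit_pca(X)
    ev <- eigen(stats::cov(X), symmetric = TRUE)$values
    expect_equal(fit$explained_variance_pct_all,
                 100 * ev / sum(ev), tolerance = 1e-9)
    ## full-rank reconstruction of the centered matrix
    full <- stats::prcomp(X, center = TRUE)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    expect_lt(max(abs(full$x %*% t(full$rotation) - Xc)), 1e-8)
  }
})

test_that("PCA handles rank-1 and degenerate data by convention", {
  v <- seq(0.1, 1, length.out = 8)
  X <- outer(c(1, 2, 3, 5), v)
  fit <- fit_pca(X)
  expect_equal(fit$explained_variance_pct_all[1], 100, tolerance = 1e-9)

  expect_error(fit_pca(matrix(1, 5, 4)), "degenerate")
  expect_error(fit_pca(matrix(rnorm(4), 2, 2)), "3 rows")
})

test_that("the sign convention makes repeated fits identical", {
  set.seed(17)
  X <- matrix(rnorm(200), 20, 10)
  f1 <- fit_pca(X); f2 <- fit_pca(X)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$loadings, f2$loadings)
  ## each loading column is unit-norm with its dominant entry positive
  for (i in seq_len(ncol(f1$loadings))) {
    expect_equal(sum(f1$loadings[, i]^2), 1, tolerance = 1e-9)
    expect_gt(f1$loadings[which.max(abs(f1$loadings[, i])), i], 0)
  }
})

test_that("an isotropic 2-D cloud splits variance evenly", {
  set.seed(41)
  fit <- fit_pca(matrix(rnorm(2e4), ncol = 2))
  expect_equal(fit$explained_variance_pct_all[1], 50, tolerance = 2)
  expect_equal(fit$explained_variance_pct_all[2], 50, tolerance = 2)
})

test_that("correlation loadings are bounded and flag degenerate channels", {
  v <- seq(0.1, 1, length.out = 8)
  X <- outer(c(1, 2, 3, 5), v) + 0  # rank-1
  fit <- fit_pca(X)
  cl <- correlation_loadings(fit, X)
  expect_true(all(abs(cl[, 1]) > 1 - 1e-9))
  expect_true(all(abs(cl) <= 1 + 1e-12, na.rm = TRUE))

  set.seed(43)
  X2 <- cbind(matrix(rnorm(3e4), ncol = 3), noise = rnorm(1e4))
  X2[, 1] <- X2[, 1] * 5
  fit2 <- fit_pca(X2)
  cl2 <- correlation_loadings(fit2, X2)
  ## a channel equal to the dominant direction correlates ~1 with PC1
  expect_gt(abs(cl2[1, 1]), 0.99)

  X3 <- cbind(X2[1:100, ], const = rep(1, 100))
  fit3 <- fit_pca(X3)
  cl3 <- correlation_loadings(fit3, X3)
  expect_true(all(is.na(cl3["const", ])))
})

test_that("pure-noise channels decorrelate from the scores", {
  set.seed(47)
  n <- 1e4
  signal <- rnorm(n)
  X <- cbind(s1 = signal, s2 = signal + rnorm(n, sd = 0.1),
             junk = rnorm(n))
  fit <- fit_pca(X)
  cl <- correlation_loadings(fit, X)
  expect_lt(abs(cl["junk", 1]), 0.05)
})

test_that("the region report covers the canonical regions per instrument", {
  sm <- pretreated_samples(3)
  rr <- region_report(sm)
  expect_equal(nrow(rr), 5)
  expect_setequal(rr$region_id, c("I", "II", "III", "IV", "V"))
  expect_true(all(rr$pc1_pct >= rr$pc2_pct))
  expect_true(all(rr$pc1_pct <= 100 & rr$pc1_pct >= 0))
})

test_that("scores are invariant to global intensity scaling when normalized", {
  cfg <- tiny_config(n = 3, replicates = 2, seed = 3)
  ds <- generate_dataset(cfg)
  scaled <- lapply(ds$spectra, function(s)
    update_spectrum(s, intensities = 7 * s$intensities))
  sm1 <- boneraman:::sample_mean_spectra(ds$spectra)
  sm2 <- boneraman:::sample_mean_spectra(scaled)
  f1 <- fit_pca(build_spectral_matrix(sm1, "V"), 2)
  f2 <- fit_pca(build_spectral_matrix(sm2, "V"), 2)
  expect_equal(f1$scores, f2$scores, tolerance = 1e-9)
})

test_that("silhouette summarises class separation in score space", {
  set.seed(53)
  scores <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
                  matrix(rnorm(40, 5, 0.1), ncol = 2))
  cl <- rep(1:2, each = 20)
  expect_gt(score_silhouette(scores, cl), 0.9)
  expect_lt(score_silhouette(matrix(rnorm(80), ncol = 2), cl), 0.2)
  expect_error(score_silhouette(scores, rep(1, 40)), "two classes")
})
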