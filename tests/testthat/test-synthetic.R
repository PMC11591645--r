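test_that("a single band renders at its nominal amplitude as resolution -> 0", {
  p <- instrument_profile("fine", 900, 1020, resolution = 0.2,
                          step = 0.2, grade = "other")
  s <- render_clean_spectrum(band_shape(958, 100, 20, eta = 0), p)
  expect_lt(abs(max(s$intensities) - 100) / 100, 0.001)
  expect_equal(s$wavenumbers[which.max(s$intensities)], 958)
})

test_that("rendering is linear: disjoint bands sum", {
  p <- handheld_profile()
  b1 <- band_shape(700, 50, 15)
  b2 <- band_shape(1600, 80, 25)
  both <- render_clean_spectrum(list(b1, b2), p)
  sum_single <- render_clean_spectrum(b1, p)$intensities +
    render_clean_spectrum(b2, p)$intensities
  expect_equal(both$intensities, sum_single, tolerance = 1e-12)
})

test_that("instrument broadening follows the Gaussian convolution closure", {
  p <- instrument_profile("fine", 400, 1600, resolution = 4,
                          step = 0.5, grade = "other")
  s <- render_clean_spectrum(band_shape(958, 100, 20, eta = 0), p)
  seg <- subtract_linear_baseline(s, band_definition("t", 958, 858, 1058))
  expect_lt(abs(fwhm(seg) - sqrt(20^2 + 4^2)) / sqrt(20^2 + 4^2), 0.01)
})

test_that("out-of-range band centers warn but still contribute tails", {
  p <- instrument_profile("narrow", 900, 1000, 2, grade = "other")
  expect_warning(s <- render_clean_spectrum(band_shape(1010, 100, 60), p),
                 "outside")
  expect_gt(max(s$intensities), 10)
})

test_that("fluorescence background obeys scale proportionality and smoothness", {
  p <- handheld_profile()
  expect_equal(render_fluorescence(p, 0)$intensities,
               rep(0, length(render_fluorescence(p, 0)$intensities)))
  b1 <- render_fluorescence(p, 1)
  b2 <- render_fluorescence(p, 2)
  a1 <- trapz(b1$wavenumbers, b1$intensities)
  a2 <- trapz(b2$wavenumbers, b2$intensities)
  expect_equal(a2 / a1, 2, tolerance = 1e-12)
  expect_true(all(b1$intensities >= 0))
  expect_error(render_fluorescence(p, -1), ">= 0")

  ## curvature bounded by the envelope polynomial: no narrow features
  coef <- c(0.2, 2.2, -1.4, 0.15, -0.05)
  u <- seq(0, 1, length.out = 2001)
  pu <- drop(outer(u, 0:4, `^`) %*% coef)
  d2max_analytic <- max(abs(drop(outer(u, 0:2, `^`) %*%
    (coef[3:5] * c(2, 6, 12))))) / max(pu)
  W <- p$range_hi - p$range_lo
  h <- p$step
  d2_emp <- max(abs(diff(b1$intensities, differences = 2))) / h^2
  expect_lt(d2_emp, 1.05 * 8 * d2max_analytic / W^2)
})

test_that("default design yields 104 samples with 5 handheld replicates", {
  cfg <- synthetic_config(instruments = list(handheld_profile()), seed = 7)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$samples), 104)
  expect_equal(sum(ds$samples$n_replicates), 520)
  expect_length(ds$spectra, 520)
  expect_equal(as.vector(table(ds$samples$pmi_class)), c(32, 46, 11, 10, 5))
  expect_true(all(vapply(ds$spectra, function(s) s$instrument, "") == "handheld"))
})

test_that("generation is deterministic and hierarchically seeded", {
  cfg <- tiny_config(n = 3, seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(
    lapply(d1$spectra, `[[`, "intensities"),
    lapply(d2$spectra, `[[`, "intensities"))

  ## growing class 4 must not perturb the samples that already existed
  cfg_big <- cfg
  cfg_big$class_sizes["4"] <- 6L
  d3 <- generate_dataset(cfg_big)
  key <- function(d) vapply(d$spectra, function(s)
    sprintf("%s_%d", s$sample_id, s$replicate_id), "")
  common <- intersect(key(d1), key(d3))
  i1 <- match(common, key(d1)); i3 <- match(common, key(d3))
  expect_identical(lapply(d1$spectra[i1], `[[`, "intensities"),
                   lapply(d3$spectra[i3], `[[`, "intensities"))
})

test_that("zero noise, zero variation, unit effects reproduce the clean render", {
  bn <- names(default_bone_bands())
  eff <- class_effect_table(
    amp_factor = matrix(1, 5, length(bn), dimnames = list(NULL, bn)),
    fwhm_shift = matrix(0, 5, length(bn), dimnames = list(NULL, bn)),
    fluor_scale = c(0, 0, 0, 0, 1),
    sample_cv = rep(0, 5))
  cfg <- tiny_config(n = 2, replicates = 2, classes = 1, effects = eff)
  cfg$noise_floor <- 0; cfg$shot_scale <- 0
  ds <- generate_dataset(cfg)
  clean <- render_clean_spectrum(default_bone_bands(), handheld_profile())
  for (s in ds$spectra)
    expect_equal(s$intensities, clean$intensities, tolerance = 1e-8)
})

test_that("class-5 spectra are fluorescence-dominated under defaults", {
  cfg <- synthetic_config(instruments = list(handheld_profile()))
  e5 <- expected_spectrum(cfg, 5)
  bg <- render_fluorescence(handheld_profile(),
                            cfg$effects$fluor_scale[5],
                            cfg$fluor_coef, cfg$fluor_peak)
  expect_gt(trapz(bg$wavenumbers, bg$intensities) /
              trapz(e5$wavenumbers, e5$intensities), 0.9)
})

test_that("the class mean converges to the expected spectrum (n = 200)", {
  cfg <- tiny_config(n = 200, replicates = 1, classes = 2, seed = 5)
  ds <- generate_dataset(cfg)
  m <- mean_spectrum(ds$spectra)
  e <- expected_spectrum(cfg, 2)
  expect_lt(max(abs(m$intensities - e$intensities)) / max(e$intensities),
            0.02)
})

test_that("effect tables validate their invariants", {
  expect_error(class_effect_table(fluor_scale = c(1, 1, 1, 1, 0.5)),
               "class-5")
  bn <- names(default_bone_bands())
  neg <- matrix(1, 5, length(bn), dimnames = list(NULL, bn))
  neg[1, 1] <- -0.1
  expect_error(class_effect_table(amp_factor = neg), ">= 0")
  expect_error(band_shape(958, -1, 10), ">= 0")
  expect_error(band_shape(958, 1, 0), "> 0")
  expect_error(band_shape(958, 1, 10, eta = 1.2), "eta")
})
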