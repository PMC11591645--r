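test_that("linear baseline subtraction zeroes endpoints and lines", {
  line <- raman_spectrum(0:10, 2 + 3 * (0:10))
  b <- band_definition("t", 5, 0, 10)
  seg <- subtract_linear_baseline(line, b)
  expect_equal(seg$intensities, rep(0, 11), tolerance = 1e-12)

  tri <- raman_spectrum(0:2, c(0, 1, 0))
  seg <- subtract_linear_baseline(tri, band_definition("t", 1, 0, 2))
  expect_equal(seg$intensities, c(0, 1, 0))

  s <- raman_spectrum(0:2, c(2, 5, 4))
  seg <- subtract_linear_baseline(s, band_definition("t", 1, 0, 2))
  expect_equal(seg$intensities, c(0, 2, 0))
  expect_equal(unname(seg$baseline), c(0, 2, 2, 4))

  expect_error(subtract_linear_baseline(tri, band_definition("t", 5, 0, 10)),
               "outside")
  two <- raman_spectrum(c(0, 10), c(1, 2))
  expect_error(subtract_linear_baseline(two, band_definition("t", 5, 0, 10)),
               "insufficient|at least")
})

test_that("the partial peak area is the direction-free trapezoidal sum", {
  expect_equal(peak_area_eq1(list(wavenumbers = 0:2,
                                  intensities = c(0, 1, 0))), 1.0)
  ## descending two-point file: |dx| = 1, mean y = 3
  expect_equal(peak_area_eq1(list(wavenumbers = c(1000, 999),
                                  intensities = c(2, 4))), 3.0)
  expect_error(peak_area_eq1(list(wavenumbers = 1, intensities = 1)),
               "2 points")

  ## analytic Gaussian integral
  x <- seq(898, 1018, by = 1)
  sg <- 20 / 2.3548
  y <- 100 * exp(-(x - 958)^2 / (2 * sg^2))
  A <- peak_area_eq1(list(wavenumbers = x, intensities = y))
  expect_lt(abs(A - 100 * sg * sqrt(2 * pi)) / (100 * sg * sqrt(2 * pi)),
            0.005)
})

test_that("the intensity sum is a plain sum, tied to area by the grid step", {
  expect_equal(intensity_sum_eq2(list(wavenumbers = 1:2,
                                      intensities = c(2, 4))), 6)
  expect_equal(intensity_sum_eq2(list(wavenumbers = 1:3,
                                      intensities = rep(0, 3))), 0)
  expect_error(intensity_sum_eq2(list(wavenumbers = numeric(0),
                                      intensities = numeric(0))), "empty")

  ## on a uniform grid of step h: A = h * Asi - h*(y1+yn)/2
  s <- gaussian_spectrum(step = 2, lo = 850, hi = 1070)
  seg <- subtract_linear_baseline(s, band_definition("t", 958, 880, 1040))
  h <- 2
  A <- peak_area_eq1(seg)
  Asi <- intensity_sum_eq2(seg)
  edge <- h * (seg$intensities[1] + seg$intensities[length(seg$intensities)]) / 2
  expect_equal(A, h * Asi - edge, tolerance = 1e-9)
})

test_that("peak height and intensity follow the stated conventions", {
  s <- gaussian_spectrum(center = 958, fwhm = 20, step = 1,
                         lo = 850, hi = 1070)
  b <- band_definition("t", 958, 898, 1018)
  seg <- subtract_linear_baseline(s, b)
  hi <- peak_height_and_intensity(seg, b)
  expect_lt(abs(hi$H - hi$I) / hi$H, 0.002)

  ## reading I at the nominal center of a shifted band undershoots H
  s2 <- gaussian_spectrum(center = 960, fwhm = 20, step = 1,
                          lo = 850, hi = 1070)
  seg2 <- subtract_linear_baseline(s2, b)
  hi2 <- peak_height_and_intensity(seg2, b)
  expect_lt(hi2$I, hi2$H)

  ## all-negative corrected segment: H = 0 convention
  dip <- raman_spectrum(0:10, c(0, -1, -2, -3, -4, -5, -4, -3, -2, -1, 0))
  segd <- subtract_linear_baseline(dip, band_definition("t", 5, 0, 10))
  expect_equal(peak_height_and_intensity(segd)$H, 0)
  m <- band_metrics(dip, band_definition("t", 5, 0, 10))
  expect_true(is.na(m$FWHM))
})

test_that("FWHM recovery matches analytic widths for both line shapes", {
  g <- gaussian_spectrum(center = 958, fwhm = 20, step = 1,
                         lo = 850, hi = 1070)
  seg <- subtract_linear_baseline(g, band_definition("t", 958, 898, 1018))
  expect_equal(fwhm(seg), 20, tolerance = 0.1 / 20)

  g6 <- gaussian_spectrum(center = 958, fwhm = 20, step = 6)
  seg6 <- subtract_linear_baseline(g6, band_definition("t", 958, 898, 1018))
  expect_equal(fwhm(seg6), 20, tolerance = 1 / 20)

  ## Lorentzian tails bias the endpoint baseline; at +-4 widths the residual
  ## tail level (1.5% of peak) keeps the width recovery inside 0.5 cm^-1
  l <- lorentzian_spectrum(center = 958, fwhm = 20, step = 1)
  segl <- subtract_linear_baseline(l, band_definition("t", 958, 878, 1038))
  expect_equal(fwhm(segl), 20, tolerance = 0.5 / 20)

  expect_error(fwhm(seg, H = 0), "> 0")
  ## flank cut off by the window: NA with warning
  wide <- subtract_linear_baseline(g, band_definition("t", 958, 952, 1018))
  expect_warning(res <- fwhm(list(wavenumbers = wide$wavenumbers,
                                  intensities = wide$raw)), "truncated")
  expect_true(is.na(res))
})

test_that("FWHM is invariant under intensity scaling and baseline offset", {
  x <- seq(850, 1070, by = 1)
  sg <- 20 / 2.3548
  base <- 100 * exp(-(x - 958)^2 / (2 * sg^2))
  b <- band_definition("t", 958, 898, 1018)
  f0 <- fwhm(subtract_linear_baseline(raman_spectrum(x, base), b))
  f_scaled <- fwhm(subtract_linear_baseline(raman_spectrum(x, 7 * base), b))
  f_offset <- fwhm(subtract_linear_baseline(
    raman_spectrum(x, base + 40 + 0.02 * x), b))
  expect_equal(f_scaled, f0, tolerance = 1e-9)
  expect_equal(f_offset, f0, tolerance = 1e-3)
})

test_that("the marker panel assembles ratios with correct homogeneity", {
  ## two pure Gaussians with equal widths and 2:1 amplitudes -> MMR = 2
  x <- seq(400, 2300, by = 1)
  sgm <- 20 / 2.3548
  y <- 100 * exp(-(x - 958)^2 / (2 * sgm^2)) +
    50 * exp(-(x - 1656)^2 / (2 * sgm^2)) +
    20 * exp(-(x - 1070)^2 / (2 * sgm^2)) +
    30 * exp(-(x - 1450)^2 / (2 * sgm^2))
  s <- raman_spectrum(x, y)
  panel <- compute_marker_panel(s)
  expect_equal(panel$MMR, 2, tolerance = 0.01)
  expect_equal(panel$carb_phos, 0.2, tolerance = 0.01)
  expect_equal(panel$min_carb, 20 / 30, tolerance = 0.01)

  ## handheld range cannot assess the C-H content
  expect_true(is.na(panel$cha_cont))
  expect_match(attr(panel, "reasons")[["cha_cont"]], "outside")

  ## global doubling: ratios fixed, intensities double
  s2 <- update_spectrum(s, intensities = 2 * y)
  p2 <- compute_marker_panel(s2)
  expect_equal(p2$MMR, panel$MMR, tolerance = 1e-9)
  expect_equal(p2$carb_phos, panel$carb_phos, tolerance = 1e-9)
  expect_equal(p2$CI, panel$CI, tolerance = 1e-9)
  expect_equal(p2$phosphate, 2 * panel$phosphate, tolerance = 1e-9)
  expect_equal(p2$amide_I, 2 * panel$amide_I, tolerance = 1e-9)
})

test_that("microscope-range spectra assess the C-H content", {
  p <- microscope_profile(1L)
  cfg <- synthetic_config(instruments = list(p))
  s <- pretreat(expected_spectrum(cfg, 1, p))
  panel <- compute_marker_panel(s)
  expect_false(is.na(panel$cha_cont))
  expect_gt(panel$cha_cont, 0)
})

test_that("non-positive denominators yield missing ratios, never zero", {
  ## spectrum with no carbonate band: A1070 ~ 0, A958 > 0
  x <- seq(400, 2300, by = 1)
  sgm <- 20 / 2.3548
  y <- 100 * exp(-(x - 958)^2 / (2 * sgm^2))
  panel <- compute_marker_panel(raman_spectrum(x, y))
  expect_true(is.na(panel$min_carb))
  expect_false(is.na(panel$phosphate))
})
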