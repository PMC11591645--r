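## Shared fixtures: all synthetic, built in code.

gaussian_spectrum <- function(center = 958, fwhm = 20, amp = 100,
                              lo = 400, hi = 2300, step = 1,
                              baseline = function(x) 0) {
  x <- seq(lo, hi, by = step)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  raman_spectrum(x, amp * exp(-(x - center)^2 / (2 * s^2)) + baseline(x))
}

lorentzian_spectrum <- function(center = 958, fwhm = 20, amp = 100,
                                lo = 400, hi = 2300, step = 1) {
  x <- seq(lo, hi, by = step)
  raman_spectrum(x, amp / (1 + 4 * ((x - center) / fwhm)^2))
}

## random smooth positive spectrum (sum of a few random Gaussians + offset)
random_spectrum <- function(seed, n_bands = 4, lo = 400, hi = 2300, step = 6) {
  set.seed(seed)
  x <- seq(lo, hi, by = step)
  y <- rep(runif(1, 0.5, 2), length(x))
  for (i in seq_len(n_bands)) {
    c0 <- runif(1, lo + 100, hi - 100)
    w <- runif(1, 15, 120)
    a <- runif(1, 5, 100)
    y <- y + a * exp(-(x - c0)^2 / (2 * (w / 2.3548)^2))
  }
  raman_spectrum(x, y)
}

## tiny 4-class generator config for structural tests
tiny_config <- function(n = 3L, replicates = 2L, seed = 1L, classes = 1:4,
                        effects = class_effect_table()) {
  sizes <- stats::setNames(integer(5), as.character(1:5))
  sizes[as.character(classes)] <- n
  synthetic_config(class_sizes = sizes,
                   instruments = list(handheld_profile(replicates)),
                   effects = effects, seed = seed)
}

## fine-grid Riemann-sum oracle for band areas: midpoint rule on a dense
## linear interpolation of the segment (independent of peak_area_eq1)
riemann_area <- function(x, y, n_fine = 20000) {
  xf <- seq(min(x), max(x), length.out = n_fine)
  h <- xf[2] - xf[1]
  mid <- (xf[-1] + xf[-n_fine]) / 2
  sum(stats::approx(x, y, xout = mid)$y * h)
}
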