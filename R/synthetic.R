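#' Instrument profile
#'
#' Describes one spectrometer: spectral range, optical resolution, sampling
#' step and replicate design. `step` defaults to the resolution; a finer step
#' can be requested for numerical studies of the forward model.
#'
#' @param name instrument identifier.
#' @param range_lo,range_hi spectral range (cm^-1).
#' @param resolution optical resolution (cm^-1), modeled as Gaussian
#'   instrument broadening of that FWHM.
#' @param replicates_per_sample replicate spectra acquired per sample.
#' @param laser_nm excitation wavelength (nm).
#' @param step sampling step of the wavenumber grid (cm^-1).
#' @param grade `"handheld"`, `"microscope"` or `"other"`; decides whether
#'   microscope-only bands are sensed.
#' @export
instrument_profile <- function(name, range_lo, range_hi, resolution,
                               replicates_per_sample = 1L, laser_nm = 785,
                               step = resolution, grade = name) {
  if (!(range_lo < range_hi)) stop("range_lo must be < range_hi")
  if (resolution <= 0 || step <= 0) stop("resolution and step must be > 0")
  structure(list(name = name, range_lo = range_lo, range_hi = range_hi,
                 resolution = resolution,
                 replicates_per_sample = as.integer(replicates_per_sample),
                 laser_nm = laser_nm, step = step, grade = grade),
            class = "instrument_profile")
}

#' @rdname instrument_profile
#' @export
handheld_profile <- function(replicates_per_sample = 5L) {
  instrument_profile("handheld", 400, 2300, 6,
                     replicates_per_sample, laser_nm = 785)
}

#' @rdname instrument_profile
#' @export
microscope_profile <- function(replicates_per_sample = 36L) {
  instrument_profile("microscope", 200, 3600, 4,
                     replicates_per_sample, laser_nm = 785)
}

#' Pseudo-Voigt band shape parameters
#'
#' @param center band center (cm^-1).
#' @param amplitude peak amplitude (arbitrary units, >= 0).
#' @param width_fwhm full width at half maximum (cm^-1, > 0).
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @param microscope_only if TRUE the band is outside the handheld
#'   instrument's effective sensitivity and renders with zero amplitude there.
#' @export
band_shape <- function(center, amplitude, width_fwhm, eta = 0.3,
                       microscope_only = FALSE) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (width_fwhm <= 0) stop("width_fwhm must be > 0")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  structure(list(center = center, amplitude = amplitude,
                 width_fwhm = width_fwhm, eta = eta,
                 microscope_only = isTRUE(microscope_only)),
            class = "band_shape")
}

#' Default bone band set for the generator
#'
#' Positions and rough relative amplitudes of the canonical bone Raman bands:
#' phosphate nu2 (450) and nu1 (958), phosphate nu4 (577, microscope only),
#' phenylalanine (1001), carbonate nu1 (1070), amide III (1246), CH2
#' deformation (1450), amide I (1656) and the C-H stretch envelope (~2930,
#' microscope only).
#'
#' @return named list of [band_shape] objects.
#' @export
default_bone_bands <- function() {
  list(
    v2PO4    = band_shape(450, 30, 14),
    v4PO4    = band_shape(577, 14, 14, microscope_only = TRUE),
    v1PO4    = band_shape(958, 100, 12),
    phe      = band_shape(1001, 7, 8),
    v1CO3    = band_shape(1070, 20, 16),
    amideIII = band_shape(1246, 18, 30),
    CH2      = band_shape(1450, 26, 22),
    amideI   = band_shape(1656, 35, 34),
    CHstr    = band_shape(2930, 45, 60, microscope_only = TRUE)
  )
}

pseudo_voigt <- function(x, center, amplitude, fwhm, eta) {
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  amplitude * (eta * l + (1 - eta) * g)
}

## Bin-integrated Gaussian broadening kernel of a given FWHM on a grid step.
broadening_kernel <- function(fwhm, step) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / step))
  edges <- (seq.int(-half, half + 1L) - 0.5) * step
  w <- diff(stats::pnorm(edges, sd = sigma))
  w / sum(w)
}

## Convolve with edge-replication padding; output length preserved.
convolve_same <- function(y, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  yp <- c(rep(y[1], half), y, rep(y[length(y)], half))
  out <- stats::filter(yp, kernel, sides = 2)
  as.numeric(out[(half + 1L):(half + length(y))])
}

band_visible <- function(band, profile) {
  !band$microscope_only || identical(profile$grade, "microscope")
}

#' Render a noiseless spectrum from band shapes
#'
#' Sum of pseudo-Voigt bands evaluated on the profile's grid, convolved with
#' a Gaussian instrument-broadening kernel of FWHM equal to the profile's
#' resolution. No noise, no background. Bands whose center falls outside the
#' profile range are still rendered (their tails may enter) with a warning.
#'
#' @param bands list of [band_shape].
#' @param profile an [instrument_profile].
#' @return a [raman_spectrum].
#' @export
render_clean_spectrum <- function(bands, profile) {
  stopifnot(inherits(profile, "instrument_profile"))
  if (inherits(bands, "band_shape")) bands <- list(bands)
  if (!length(bands)) stop("need at least one band")
  grid <- seq(profile$range_lo, profile$range_hi, by = profile$step)
  y <- numeric(length(grid))
  for (b in bands) {
    if (!band_visible(b, profile)) next
    if (b$center < profile$range_lo || b$center > profile$range_hi)
      warning(sprintf("band center %g cm^-1 outside profile range [%g, %g]",
                      b$center, profile$range_lo, profile$range_hi))
    y <- y + pseudo_voigt(grid, b$center, b$amplitude, b$width_fwhm, b$eta)
  }
  y <- convolve_same(y, broadening_kernel(profile$resolution, profile$step))
  raman_spectrum(grid, y, instrument = profile$name,
                 metadata = list(resolution = profile$resolution))
}

#' Render a fluorescence background
#'
#' A smooth, broad, non-negative single-humped envelope: a 4th-order
#' polynomial in the normalized position across the profile range, scaled so
#' its peak equals `peak_height` at `scale = 1`. Integrated area is exactly
#' proportional to `scale`.
#'
#' @param profile an [instrument_profile].
#' @param scale non-negative scale factor.
#' @param coef polynomial coefficients (constant first) of the envelope in
#'   the unit interval; the evaluated envelope is clipped at zero.
#' @param peak_height background peak height (arbitrary units) at scale 1.
#' @return a [raman_spectrum].
#' @export
render_fluorescence <- function(profile, scale,
                                coef = c(0.2, 2.2, -1.4, 0.15, -0.05),
                                peak_height = 8) {
  stopifnot(inherits(profile, "instrument_profile"))
  if (!is.finite(scale) || scale < 0) stop("fluorescence scale must be >= 0")
  grid <- seq(profile$range_lo, profile$range_hi, by = profile$step)
  u <- (grid - profile$range_lo) / (profile$range_hi - profile$range_lo)
  p <- pmax(0, drop(outer(u, seq_along(coef) - 1, `^`) %*% coef))
  if (max(p) > 0) p <- p / max(p)
  raman_spectrum(grid, scale * peak_height * p, instrument = profile$name,
                 metadata = list(resolution = profile$resolution))
}

#' Per-class effect table of the generator
#'
#' Encodes how each PMI class (1-5) perturbs the base band set: a
#' multiplicative amplitude factor and an additive FWHM shift per band, plus
#' a per-class fluorescence scale and between-sample coefficient of
#' variation. The default trends follow the qualitative diagenesis picture:
#' mineral and organic band amplitudes decrease with PMI (amide I most
#' strongly), carbonate substitution increases, the phosphate band broadens
#' (crystallinity falls), and fluorescence grows with age until it dominates
#' class 5.
#'
#' @param amp_factor classes x bands matrix of amplitude factors (>= 0).
#' @param fwhm_shift classes x bands matrix of additive FWHM shifts (cm^-1).
#' @param fluor_scale per-class fluorescence scale; class 5 must exceed
#'   classes 1-4.
#' @param sample_cv per-class between-sample coefficient of variation of band
#'   amplitudes (lognormal, mean 1).
#' @export
class_effect_table <- function(amp_factor = NULL, fwhm_shift = NULL,
                               fluor_scale = c(0.2, 0.4, 0.7, 1.0, 20),
                               sample_cv = rep(0.08, 5)) {
  bn <- names(default_bone_bands())
  if (is.null(amp_factor)) {
    amp_factor <- rbind(
      v2PO4    = c(1.00, 0.95, 0.90, 0.85, 0.80),
      v4PO4    = c(1.00, 0.95, 0.90, 0.85, 0.80),
      v1PO4    = c(1.00, 0.93, 0.89, 0.86, 0.80),
      phe      = c(1.00, 1.00, 1.00, 1.00, 1.00),
      v1CO3    = c(1.00, 1.08, 1.14, 1.22, 1.25),
      amideIII = c(1.00, 0.90, 0.82, 0.75, 0.60),
      CH2      = c(1.00, 0.92, 0.86, 0.80, 0.70),
      amideI   = c(1.00, 0.80, 0.65, 0.55, 0.40),
      CHstr    = c(1.00, 0.90, 0.80, 0.70, 0.55))
    amp_factor <- t(amp_factor)[, bn]
  }
  if (is.null(fwhm_shift)) {
    fwhm_shift <- matrix(0, 5, length(bn), dimnames = list(NULL, bn))
    fwhm_shift[, "v1PO4"] <- c(0, 1, 2, 3, 4)
  }
  stopifnot(nrow(amp_factor) == 5, nrow(fwhm_shift) == 5,
            length(fluor_scale) == 5, length(sample_cv) == 5)
  if (any(amp_factor < 0) || any(fluor_scale < 0) || any(sample_cv < 0))
    stop("all effect factors must be >= 0")
  if (fluor_scale[5] <= max(fluor_scale[1:4]))
    stop("class-5 fluorescence scale must exceed classes 1-4")
  structure(list(amp_factor = amp_factor, fwhm_shift = fwhm_shift,
                 fluor_scale = fluor_scale, sample_cv = sample_cv),
            class = "class_effect_table")
}

#' @rdname class_effect_table
#' @details `null_effect_table()` is the no-class-effect version used for
#'   type-I-error calibration: unit amplitude factors, zero FWHM shifts and a
#'   common low fluorescence level for classes 1-4.
#' @export
null_effect_table <- function() {
  bn <- names(default_bone_bands())
  class_effect_table(
    amp_factor = matrix(1, 5, length(bn), dimnames = list(NULL, bn)),
    fwhm_shift = matrix(0, 5, length(bn), dimnames = list(NULL, bn)),
    fluor_scale = c(0.2, 0.2, 0.2, 0.2, 0.25),
    sample_cv = rep(0.08, 5))
}

#' Synthetic study configuration
#'
#' Everything the generator needs: per-class sample counts (default: the
#' study design 32/46/11/10/5), instrument profiles to render, the class
#' effect table, fluorescence and noise models, and the master seed.
#'
#' @param class_sizes named integer vector, classes "1".."5".
#' @param instruments list of [instrument_profile] objects.
#' @param bands base band set, as [default_bone_bands()].
#' @param effects a [class_effect_table].
#' @param fluor_coef,fluor_peak fluorescence envelope parameters
#'   (see [render_fluorescence]).
#' @param noise_floor additive Gaussian noise floor (counts).
#' @param shot_scale shot-noise coefficient: sd contribution
#'   `shot_scale * sqrt(intensity)`.
#' @param female_fraction fraction of female samples in the metadata draw.
#' @param seed master seed; drives a hierarchical stream
#'   (dataset -> sample -> replicate) so growing a class does not perturb
#'   existing samples.
#' @export
synthetic_config <- function(class_sizes = c(`1` = 32L, `2` = 46L, `3` = 11L,
                                             `4` = 10L, `5` = 5L),
                             instruments = list(handheld_profile(),
                                                microscope_profile()),
                             bands = default_bone_bands(),
                             effects = class_effect_table(),
                             fluor_coef = c(0.2, 2.2, -1.4, 0.15, -0.05),
                             fluor_peak = 8,
                             noise_floor = 0.3,
                             shot_scale = 0.15,
                             female_fraction = 16 / 104,
                             seed = 1L) {
  if (inherits(instruments, "instrument_profile")) instruments <- list(instruments)
  stopifnot(all(class_sizes >= 0), all(names(class_sizes) %in% as.character(1:5)))
  stopifnot(inherits(effects, "class_effect_table"))
  structure(list(class_sizes = class_sizes, instruments = instruments,
                 bands = bands, effects = effects, fluor_coef = fluor_coef,
                 fluor_peak = fluor_peak, noise_floor = noise_floor,
                 shot_scale = shot_scale, female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## Per-instrument render cache: unit-amplitude convolved band shapes per
## class (columns = bands; microscope-only bands zeroed where not sensed)
## and the unit fluorescence background.
build_render_cache <- function(cfg, profile) {
  bn <- names(cfg$bands)
  classes <- as.integer(names(cfg$class_sizes)[cfg$class_sizes > 0])
  grid <- seq(profile$range_lo, profile$range_hi, by = profile$step)
  M <- vector("list", 5L)
  for (cl in classes) {
    cols <- matrix(0, length(grid), length(bn), dimnames = list(NULL, bn))
    for (j in seq_along(bn)) {
      b <- cfg$bands[[j]]
      if (!band_visible(b, profile)) next
      ub <- band_shape(b$center, 1,
                       b$width_fwhm + cfg$effects$fwhm_shift[cl, bn[j]],
                       b$eta, b$microscope_only)
      cols[, j] <- suppressWarnings(
        render_clean_spectrum(list(ub), profile))$intensities
    }
    M[[cl]] <- cols
  }
  fl <- render_fluorescence(profile, 1, cfg$fluor_coef, cfg$fluor_peak)
  list(grid = grid, M = M, fluor_unit = fl$intensities,
       base_amp = vapply(cfg$bands, `[[`, 0, "amplitude"))
}

#' Generate a synthetic bone Raman dataset
#'
#' For every class and sample: sample-level band amplitudes are drawn as
#' base amplitude x class factor x lognormal (mean-1) between-sample
#' variation, shared across instruments (one piece of bone, two devices).
#' Each replicate adds independent Gaussian noise with
#' `sd = noise_floor + shot_scale * sqrt(intensity)` on top of the clean
#' render plus the class-scaled fluorescence background. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [synthetic_config].
#' @return list with `spectra` (list of [raman_spectrum]) and `samples`
#'   (sample table data.frame).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  caches <- lapply(cfg$instruments, function(p) build_render_cache(cfg, p))
  classes <- as.integer(names(cfg$class_sizes)[cfg$class_sizes > 0])
  spectra <- list()
  rows <- list()
  for (cl in classes) {
    n_cl <- cfg$class_sizes[[as.character(cl)]]
    cv <- cfg$effects$sample_cv[cl]
    sl <- sqrt(log(1 + cv^2))
    for (j in seq_len(n_cl)) {
      sid <- sprintf("C%d_S%03d", cl, j)
      sseed <- derive_seed(cfg$seed, cl, j)
      set.seed(sseed)
      nb <- length(cfg$bands)
      jit <- exp(stats::rnorm(nb, -0.5 * sl^2, sl))
      fjit <- exp(stats::rnorm(1, -0.5 * sl^2, sl))
      sex <- if (stats::runif(1) < cfg$female_fraction) "F" else "M"
      for (k in seq_along(cfg$instruments)) {
        prof <- cfg$instruments[[k]]
        cache <- caches[[k]]
        amps <- cache$base_amp * cfg$effects$amp_factor[cl, ] * jit
        clean <- drop(cache$M[[cl]] %*% amps) +
          cfg$effects$fluor_scale[cl] * fjit * cache$fluor_unit
        sd_vec <- cfg$noise_floor + cfg$shot_scale * sqrt(pmax(clean, 0))
        for (r in seq_len(prof$replicates_per_sample)) {
          set.seed(derive_seed(sseed, k, r))
          y <- clean + stats::rnorm(length(clean), 0, sd_vec)
          spectra[[length(spectra) + 1L]] <- raman_spectrum(
            cache$grid, y, instrument = prof$name, sample_id = sid,
            replicate_id = r, pmi_class = cl,
            metadata = list(resolution = prof$resolution, seed = cfg$seed))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, pmi_class = cl, sex = sex,
          instrument = prof$name,
          n_replicates = prof$replicates_per_sample)
      }
    }
  }
  samples <- do.call(rbind, rows)
  validate_sample_table(samples)
  list(spectra = spectra, samples = samples)
}

#' Expected (noise-free) spectrum of a class
#'
#' The clean render with class-mean band parameters plus the class-mean
#' fluorescence background: the generator's ground truth against which
#' recovered markers are judged.
#'
#' @param cfg a [synthetic_config].
#' @param pmi_class class in 1..5.
#' @param profile an [instrument_profile] (default: first in `cfg`).
#' @export
expected_spectrum <- function(cfg, pmi_class, profile = cfg$instruments[[1]]) {
  cache <- build_render_cache_for_class(cfg, profile, pmi_class)
  amps <- cache$base_amp * cfg$effects$amp_factor[pmi_class, ]
  y <- drop(cache$M[[pmi_class]] %*% amps) +
    cfg$effects$fluor_scale[pmi_class] * cache$fluor_unit
  raman_spectrum(cache$grid, y, instrument = profile$name,
                 pmi_class = pmi_class,
                 metadata = list(resolution = profile$resolution))
}

build_render_cache_for_class <- function(cfg, profile, pmi_class) {
  cfg2 <- cfg
  cs <- stats::setNames(integer(5), as.character(1:5))
  cs[as.character(pmi_class)] <- 1L
  cfg2$class_sizes <- cs
  build_render_cache(cfg2, profile)
}

#' Ground-truth marker panel per class
#'
#' Runs the pretreatment and marker extraction on each class's expected
#' spectrum, giving the marker values an unbiased estimator should recover.
#'
#' @param cfg a [synthetic_config].
#' @param profile an [instrument_profile].
#' @param record the [pretreatment_record] used in the pipeline.
#' @param bands marker band definitions.
#' @param classes classes to include.
#' @export
marker_ground_truth <- function(cfg, profile = cfg$instruments[[1]],
                                record = pretreatment_record(),
                                bands = default_bands(),
                                classes = NULL) {
  if (is.null(classes))
    classes <- as.integer(names(cfg$class_sizes)[cfg$class_sizes > 0])
  out <- lapply(classes, function(cl) {
    s <- pretreat(expected_spectrum(cfg, cl, profile), record)
    cbind(pmi_class = cl, compute_marker_panel(s, bands))
  })
  do.call(rbind, out)
}
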