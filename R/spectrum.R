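#' Construct a Raman spectrum
#'
#' The basic data container of the package: one replicate measurement with a
#' wavenumber axis in cm^-1 and an intensity vector in arbitrary counts.
#' Axes are canonicalized to ascending order on construction; the original
#' direction is recorded in `metadata$axis_direction` so nothing downstream
#' ever depends on the direction a vendor file happened to use.
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotonic (either direction).
#' @param intensities numeric vector of intensities, same length, all finite.
#'   Negative values are allowed (they occur after baseline subtraction and
#'   under detector noise).
#' @param instrument instrument identifier, e.g. `"handheld"`, `"microscope"`.
#' @param sample_id sample identifier.
#' @param replicate_id integer replicate index within the sample.
#' @param pmi_class optional post-mortem interval class in 1..5.
#' @param normalized logical; has the spectrum been area-normalized?
#' @param metadata free-form list of additional metadata.
#' @return an object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities,
                           instrument = "other",
                           sample_id = NA_character_,
                           replicate_id = NA_integer_,
                           pmi_class = NA_integer_,
                           normalized = FALSE,
                           metadata = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(intensities)))
    stop("wavenumbers and intensities must be finite")
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    direction <- "ascending"
  } else if (all(d < 0)) {
    direction <- "descending"
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
  } else {
    stop("wavenumber axis must be strictly monotonic")
  }
  if (!is.na(pmi_class) && !(pmi_class %in% 1:5))
    stop("pmi_class must be in 1..5")
  metadata$axis_direction <- metadata$axis_direction %||% direction
  structure(
    list(wavenumbers = wavenumbers,
         intensities = intensities,
         instrument = instrument,
         sample_id = sample_id,
         replicate_id = as.integer(replicate_id),
         pmi_class = as.integer(pmi_class),
         normalized = isTRUE(normalized),
         metadata = metadata),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s | sample %s rep %s | class %s\n",
              x$instrument, x$sample_id, x$replicate_id, x$pmi_class))
  cat(sprintf("  %d points, %.1f-%.1f cm^-1%s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              if (x$normalized) ", area-normalized" else ""))
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, intensity = x$intensities)
}

## Copy a spectrum replacing its data while keeping metadata.
update_spectrum <- function(s, wavenumbers = s$wavenumbers,
                            intensities = s$intensities,
                            normalized = s$normalized,
                            metadata = s$metadata) {
  raman_spectrum(wavenumbers, intensities,
                 instrument = s$instrument, sample_id = s$sample_id,
                 replicate_id = s$replicate_id, pmi_class = s$pmi_class,
                 normalized = normalized, metadata = metadata)
}

#' Resample a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto `seq(grid_lo, grid_hi, by = step)`. Needed to
#' place replicate spectra on one axis before averaging and PCA.
#'
#' @param s a [raman_spectrum].
#' @param grid_lo,grid_hi grid limits (cm^-1); must lie inside the span of `s`.
#' @param step grid step (cm^-1), > 0.
#' @return a [raman_spectrum] on the requested grid.
#' @export
resample_to_grid <- function(s, grid_lo, grid_hi, step) {
  stopifnot(inherits(s, "raman_spectrum"), step > 0, grid_lo < grid_hi)
  lo <- min(s$wavenumbers); hi <- max(s$wavenumbers)
  if (grid_lo < lo - 1e-9 || grid_hi > hi + 1e-9)
    stop(sprintf("requested range [%g, %g] outside spectrum span [%g, %g]",
                 grid_lo, grid_hi, lo, hi))
  grid <- seq(grid_lo, grid_hi, by = step)
  y <- stats::approx(s$wavenumbers, s$intensities, xout = grid, rule = 1)$y
  update_spectrum(s, wavenumbers = grid, intensities = y)
}

## Extract the window [lo, hi] of a spectrum as index range.
window_indices <- function(s, lo, hi) {
  which(s$wavenumbers >= lo - 1e-9 & s$wavenumbers <= hi + 1e-9)
}
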