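#' Fluorescence-dominance fraction of a spectrum
#'
#' Estimates how much of a spectrum's area is broad background rather than
#' Raman bands: the baseline is an iterated rolling minimum (window of about
#' 200 cm^-1) followed by rolling-mean smoothing, and the fraction is
#' baseline area over total area, clipped to `[0, 1]`. Scale-invariant by
#' construction. This is a usability gate, not a fluorescence correction: the
#' estimated baseline is never subtracted from the data.
#'
#' @param s a [raman_spectrum] with >= 50 points.
#' @param window_cm rolling window width in cm^-1.
#' @return fraction in `[0, 1]`.
#' @export
fluorescence_fraction <- function(s, window_cm = 200) {
  stopifnot(inherits(s, "raman_spectrum"))
  n <- length(s$wavenumbers)
  if (n < 50L) stop("fluorescence_fraction needs >= 50 points")
  y <- pmax(s$intensities, 0)
  total <- trapz(s$wavenumbers, y)
  if (total <= 0) stop("degenerate spectrum: non-positive total area")
  step <- stats::median(diff(s$wavenumbers))
  k <- max(3L, round(window_cm / step))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, n)
  ## morphological opening: the rolling minimum erases features narrower
  ## than the window, the rolling maximum undoes the erosion bias on smooth
  ## broad backgrounds; a rolling mean smooths the residual staircase
  base <- zoo::rollapply(y, k, min, partial = TRUE)
  base <- zoo::rollapply(base, k, max, partial = TRUE)
  base <- zoo::rollapply(base, k, mean, partial = TRUE)
  base <- pmin(base, y + 1e-12 * max(y))
  frac <- trapz(s$wavenumbers, pmax(base, 0)) / total
  min(max(frac, 0), 1)
}

#' Quality-control gate against fluorescence dominance
#'
#' Partitions replicate spectra into usable and unusable by their
#' fluorescence fraction (and, optionally, by requiring positive
#' baseline-corrected peak height in a set of required bands). Downstream
#' marker extraction and PCA consume only the usable list; this is how
#' archeological-grade, fluorescence-swamped spectra are kept out of the
#' statistics.
#'
#' @param spectra list of [raman_spectrum].
#' @param threshold maximum tolerated fluorescence fraction, in (0, 1].
#' @param required_bands optional list of [band_definition]; each must show
#'   positive baseline-corrected height for a spectrum to pass.
#' @param window_cm passed to [fluorescence_fraction].
#' @return list with `usable` (spectra passing) and `results` (QC table).
#' @export
qc_gate <- function(spectra, threshold = 0.9, required_bands = NULL,
                    window_cm = 200) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  res <- lapply(spectra, function(s) {
    frac <- fluorescence_fraction(s, window_cm)
    reason <- ""
    ok <- frac <= threshold
    if (!ok) reason <- sprintf("fluorescence fraction %.3f > %.2f",
                               frac, threshold)
    if (ok && length(required_bands)) {
      for (b in required_bands) {
        h <- tryCatch({
          seg <- subtract_linear_baseline(s, b)
          peak_height_and_intensity(seg, b)$H
        }, error = function(e) NA_real_)
        if (is.na(h) || h <= 0) {
          ok <- FALSE
          reason <- sprintf("band %s has no positive corrected height", b$name)
          break
        }
      }
    }
    data.frame(sample_id = s$sample_id, replicate_id = s$replicate_id,
               instrument = s$instrument, pmi_class = s$pmi_class,
               fluorescence_fraction = frac, usable = ok, reason = reason)
  })
  results <- do.call(rbind, res)
  list(usable = spectra[results$usable], results = results)
}
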