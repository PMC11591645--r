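#' Pretreatment record
#'
#' Bundles the pretreatment chain applied to every spectrum before metric
#' extraction and PCA: point reduction, Savitzky-Golay smoothing and area
#' normalization, applied in that order. The record travels with each
#' pretreated spectrum (in its metadata) so downstream stages can refuse to
#' mix spectra with different provenance.
#'
#' @param reduction_factor integer >= 1; block size for point reduction.
#' @param sg_window odd integer, Savitzky-Golay window length in points.
#' @param sg_polyorder polynomial order, < `sg_window`.
#' @param normalization `"area"` or `"none"`.
#' @export
pretreatment_record <- function(reduction_factor = 1L, sg_window = 5L,
                                sg_polyorder = 2L,
                                normalization = c("area", "none")) {
  normalization <- match.arg(normalization)
  reduction_factor <- as.integer(reduction_factor)
  sg_window <- as.integer(sg_window)
  if (reduction_factor < 1L) stop("reduction_factor must be >= 1")
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder)
    stop("sg_window must be odd and greater than sg_polyorder")
  structure(list(reduction_factor = reduction_factor, sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 normalization = normalization),
            class = "pretreatment_record")
}

#' Reduce spectral points by block averaging
#'
#' Consecutive non-overlapping blocks of `factor` points are replaced by their
#' (mean wavenumber, mean intensity); a trailing partial block is averaged
#' as-is. The anti-aliasing interpretation of a spectral "reduction factor".
#'
#' @param s a [raman_spectrum].
#' @param factor integer >= 1.
#' @export
reduce_points <- function(s, factor) {
  stopifnot(inherits(s, "raman_spectrum"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("validation error: factor must be >= 1")
  if (factor == 1L) return(s)
  n <- length(s$wavenumbers)
  if (n < factor) stop("spectrum shorter than reduction factor")
  if (ceiling(n / factor) < 2L)
    stop("reduction would leave fewer than 2 points")
  g <- (seq_len(n) - 1L) %/% factor
  cnt <- tabulate(g + 1L)
  w <- rowsum(s$wavenumbers, g)[, 1] / cnt
  y <- rowsum(s$intensities, g)[, 1] / cnt
  update_spectrum(s, wavenumbers = w, intensities = y)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing on a uniform axis, with fit-based
#' (polynomial-extension) edge handling, exact on polynomials up to
#' `polyorder` everywhere.
#'
#' @param s a [raman_spectrum] on a uniform grid (relative tolerance 1e-6).
#' @param window odd window length in points, <= length of spectrum.
#' @param polyorder polynomial order < window.
#' @export
savitzky_golay <- function(s, window = 15L, polyorder = 2L) {
  stopifnot(inherits(s, "raman_spectrum"))
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= polyorder)
    stop("window must be odd and greater than polyorder")
  if (window > length(s$intensities))
    stop(sprintf("window (%d points) exceeds spectrum length (%d)",
                 window, length(s$intensities)))
  if (!is_uniform_axis(s$wavenumbers))
    stop("non-uniform wavenumber axis; apply resample_to_grid() first")
  y <- signal::sgolayfilt(s$intensities, sgolay_matrix(polyorder, window))
  update_spectrum(s, intensities = y)
}

## Cache the SG projection matrix per (order, window): its construction (an
## SVD per row) dominates repeated smoothing of short spectra.
.sg_cache <- new.env(parent = emptyenv())
sgolay_matrix <- function(p, n) {
  key <- sprintf("p%d_n%d", p, n)
  m <- .sg_cache[[key]]
  if (is.null(m)) {
    m <- signal::sgolay(p = p, n = n)
    .sg_cache[[key]] <- m
  }
  m
}

#' Area normalization
#'
#' Divides intensities by the trapezoidal integral over the full axis, so the
#' post-normalization integral is 1. Makes peak areas comparable across
#' samples where excitation volume and focus vary.
#'
#' @param s a [raman_spectrum].
#' @export
area_normalize <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  total_abs <- trapz(s$wavenumbers, abs(s$intensities))
  total <- trapz(s$wavenumbers, s$intensities)
  if (total_abs <= 0 || abs(total) < 1e-12 * max(total_abs, 1))
    stop("degenerate spectrum: integral too close to zero to normalize")
  update_spectrum(s, intensities = s$intensities / total, normalized = TRUE)
}

#' Apply the full pretreatment chain
#'
#' reduce -> smooth -> normalize, attaching the [pretreatment_record] to the
#' output's metadata.
#'
#' @param s a [raman_spectrum].
#' @param record a [pretreatment_record].
#' @export
pretreat <- function(s, record = pretreatment_record()) {
  stopifnot(inherits(record, "pretreatment_record"))
  out <- reduce_points(s, record$reduction_factor)
  out <- savitzky_golay(out, record$sg_window, record$sg_polyorder)
  if (record$normalization == "area") out <- area_normalize(out)
  out$metadata$pretreatment <- unclass(record)
  out
}

#' Pointwise mean spectrum of a group
#'
#' Spectra are resampled onto the intersection grid (finest common step) and
#' averaged pointwise. Used for replicate means and per-class mean spectra.
#'
#' @param group non-empty list of [raman_spectrum] sharing one instrument.
#' @param label optional group label stored in metadata.
#' @export
mean_spectrum <- function(group, label = NULL) {
  if (!length(group)) stop("empty group")
  stopifnot(all(vapply(group, inherits, TRUE, "raman_spectrum")))
  instr <- unique(vapply(group, `[[`, "", "instrument"))
  if (length(instr) > 1L)
    stop("mean_spectrum: spectra from different instruments: ",
         paste(instr, collapse = ", "))
  lo <- max(vapply(group, function(s) min(s$wavenumbers), 0))
  hi <- min(vapply(group, function(s) max(s$wavenumbers), 0))
  if (lo >= hi) stop("spectra have disjoint wavenumber ranges")
  ## reuse the common axis if shared; otherwise build an intersection grid
  ax <- group[[1]]$wavenumbers
  shared <- all(vapply(group, function(s)
    length(s$wavenumbers) == length(ax) &&
      max(abs(s$wavenumbers - ax)) < 1e-9, TRUE))
  if (shared) {
    grid <- ax
    ymat <- vapply(group, `[[`, numeric(length(ax)), "intensities")
  } else {
    step <- min(vapply(group, function(s) stats::median(diff(s$wavenumbers)), 0))
    grid <- seq(lo, hi, by = step)
    ymat <- vapply(group, function(s)
      stats::approx(s$wavenumbers, s$intensities, xout = grid)$y,
      numeric(length(grid)))
  }
  s1 <- group[[1]]
  md <- s1$metadata
  md$group <- label %||% sprintf("mean of %d spectra", length(group))
  raman_spectrum(grid, rowMeans(ymat),
                 instrument = instr, sample_id = s1$sample_id,
                 replicate_id = NA_integer_, pmi_class = s1$pmi_class,
                 normalized = all(vapply(group, `[[`, TRUE, "normalized")),
                 metadata = md)
}
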