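#' Band definition
#'
#' A named Raman band with its nominal center and the integration window used
#' for baseline subtraction and metric extraction.
#'
#' @param name band name.
#' @param center nominal band position (cm^-1).
#' @param window_lo,window_hi window limits (cm^-1), with
#'   `window_lo < center < window_hi`.
#' @export
band_definition <- function(name, center, window_lo, window_hi) {
  if (!(window_lo < center && center < window_hi))
    stop("band window must satisfy window_lo < center < window_hi")
  structure(list(name = name, center = center,
                 window_lo = window_lo, window_hi = window_hi),
            class = "band_definition")
}

#' Default diagnostic band set for bone
#'
#' Windows for the phosphate, carbonate, amide and CH bands used by the
#' six-marker panel. The C-H stretch window (2800-3000 cm^-1) is only
#' reachable by the microscope's range.
#'
#' @return named list of [band_definition] objects.
#' @export
default_bands <- function() {
  list(
    v2PO4   = band_definition("v2PO4",   450, 420, 480),
    v1PO4   = band_definition("v1PO4",   958, 920, 990),
    v1CO3   = band_definition("v1CO3",  1070, 1040, 1100),
    amideIII = band_definition("amideIII", 1246, 1200, 1320),
    CH2     = band_definition("CH2",    1450, 1410, 1490),
    amideI  = band_definition("amideI", 1656, 1550, 1730),
    CH      = band_definition("CH",     2930, 2800, 3000)
  )
}

#' Linear baseline subtraction over a band window
#'
#' Returns the window segment with the straight line through its first and
#' last (x, y) points subtracted, the spreadsheet-style baseline used before
#' all peak arithmetic. Endpoint residuals are exactly zero.
#'
#' @param s a [raman_spectrum].
#' @param band a [band_definition] (window must lie inside the spectrum span).
#' @return a `raman_segment`: list with `wavenumbers`, `intensities`
#'   (baseline-corrected), `raw`, and the baseline endpoints used.
#' @export
subtract_linear_baseline <- function(s, band) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(band, "band_definition"))
  idx <- window_indices(s, band$window_lo, band$window_hi)
  if (!length(idx) || min(s$wavenumbers) > band$window_lo ||
      max(s$wavenumbers) < band$window_hi)
    stop(sprintf("band window [%g, %g] outside spectrum span [%g, %g]",
                 band$window_lo, band$window_hi,
                 min(s$wavenumbers), max(s$wavenumbers)))
  if (length(idx) < 3L)
    stop("insufficient points in band window (need >= 3)")
  x <- s$wavenumbers[idx]; y <- s$intensities[idx]
  n <- length(x)
  slope <- (y[n] - y[1]) / (x[n] - x[1])
  baseline <- y[1] + slope * (x - x[1])
  structure(list(wavenumbers = x, intensities = y - baseline, raw = y,
                 baseline = c(x1 = x[1], y1 = y[1], xn = x[n], yn = y[n]),
                 band = band),
            class = "raman_segment")
}

seg_xy <- function(segment) {
  if (inherits(segment, "raman_segment"))
    list(x = segment$wavenumbers, y = segment$intensities)
  else if (is.list(segment) && !is.null(segment$wavenumbers))
    list(x = segment$wavenumbers, y = segment$intensities)
  else stop("expected a raman_segment")
}

#' Partial peak area (trapezoidal sum)
#'
#' The spreadsheet partial-area rule: the sum over consecutive point pairs of
#' `(y[i-1] + y[i]) * |x[i-1] - x[i]| / 2`. Absolute spacing makes the value
#' independent of file axis direction. Negative areas of degenerate windows
#' are reported as-is.
#'
#' @param segment a baseline-corrected `raman_segment` (>= 2 points).
#' @export
peak_area_eq1 <- function(segment) {
  p <- seg_xy(segment)
  if (length(p$x) < 2L) stop("peak area needs at least 2 points")
  trapz(p$x, p$y)
}

#' Total intensity sum
#'
#' The plain sum of segment intensities, the second (grid-step-free) area
#' convention of the spreadsheet method.
#'
#' @param segment a `raman_segment` (>= 1 point).
#' @export
intensity_sum_eq2 <- function(segment) {
  p <- seg_xy(segment)
  if (!length(p$y)) stop("empty segment")
  sum(p$y)
}

#' Peak height and intensity of a band segment
#'
#' `H` is the maximum baseline-corrected intensity in the window; `I` is the
#' corrected intensity at the grid point nearest the band's nominal center,
#' which keeps intensity markers comparable across samples whose maxima
#' wander. When the corrected segment is entirely <= 0, `H` is 0 by
#' convention.
#'
#' @param segment a baseline-corrected `raman_segment`.
#' @param band the [band_definition] (for the nominal center).
#' @return list with `H`, `I`, `at` (wavenumber of the maximum).
#' @export
peak_height_and_intensity <- function(segment, band = segment$band) {
  p <- seg_xy(segment)
  imax <- which.max(p$y)
  H <- max(p$y[imax], 0)
  ic <- which.min(abs(p$x - band$center))
  list(H = H, I = p$y[ic], at = p$x[imax])
}

#' Full width at half maximum of a band segment
#'
#' Width between the two half-maximum crossings, located by linear
#' interpolation on each flank of the maximum. If a flank never crosses H/2
#' inside the window the width is NA with a flank-truncation warning.
#'
#' @param segment a baseline-corrected `raman_segment`.
#' @param H the peak height (must be > 0).
#' @export
fwhm <- function(segment, H = NULL) {
  p <- seg_xy(segment)
  if (is.null(H)) H <- max(p$y)
  if (!is.finite(H) || H <= 0) stop("FWHM undefined: peak height must be > 0")
  half <- H / 2
  im <- which.max(p$y)
  cross <- function(idx_seq) {
    for (i in idx_seq) {
      lo <- min(i, i + 1L); hi <- max(i, i + 1L)
      y0 <- p$y[lo]; y1 <- p$y[hi]
      if ((y0 - half) * (y1 - half) <= 0 && y0 != y1) {
        return(p$x[lo] + (half - y0) / (y1 - y0) * (p$x[hi] - p$x[lo]))
      }
    }
    NA_real_
  }
  left <- if (im > 1L) cross(seq.int(im - 1L, 1L)) else NA_real_
  right <- if (im < length(p$y)) cross(seq.int(im, length(p$y) - 1L)) else NA_real_
  if (is.na(left) || is.na(right)) {
    warning("FWHM flank truncated by window; returning NA")
    return(NA_real_)
  }
  right - left
}

#' All metrics for one band
#'
#' Runs baseline subtraction and extracts H, I, A (partial area), Asi
#' (intensity sum) and FWHM for a band.
#'
#' @param s a [raman_spectrum].
#' @param band a [band_definition].
#' @return list of class `peak_metrics`.
#' @export
band_metrics <- function(s, band) {
  seg <- subtract_linear_baseline(s, band)
  hi <- peak_height_and_intensity(seg, band)
  fw <- if (hi$H > 0) suppressWarnings(fwhm(seg, hi$H)) else NA_real_
  structure(list(band = band$name, H = hi$H, I = hi$I,
                 A = peak_area_eq1(seg), Asi = intensity_sum_eq2(seg),
                 FWHM = fw, baseline = seg$baseline),
            class = "peak_metrics")
}

#' Six-marker bone-quality panel
#'
#' Assembles the diagnostic panel from one (pretreated) spectrum:
#' \describe{
#'   \item{phosphate}{I at 958 cm^-1 (amount of phosphate)}
#'   \item{CI}{crystallinity index, 1/FWHM of the 958 band (per cm)}
#'   \item{MMR}{mineral-to-matrix ratio A958/A1656}
#'   \item{carb_phos}{carbonate-to-phosphate ratio A1070/A958}
#'   \item{min_carb}{mineral carbonate content A1070/A1450}
#'   \item{amide_I}{I at 1656 cm^-1 (collagen)}
#'   \item{cha_cont}{C-H aliphatic area fraction over 2800-3000 cm^-1,
#'     computable only when that window lies inside the instrument range
#'     (microscope); otherwise NA}
#' }
#' Ratios with non-positive denominators and metrics whose windows fall
#' outside the spectrum are NA, never 0; reasons are attached as the
#' `"reasons"` attribute.
#'
#' @param s a [raman_spectrum], typically pretreated.
#' @param bands band set as from [default_bands()].
#' @return one-row data.frame of markers.
#' @export
compute_marker_panel <- function(s, bands = default_bands()) {
  v <- marker_vector(s, bands)
  out <- as.data.frame(as.list(v))
  attr(out, "reasons") <- attr(v, "reasons")
  out
}

## Fast path: the marker panel as a named numeric vector (used in simulation
## loops where data.frame construction per sample is measurable).
marker_vector <- function(s, bands = default_bands()) {
  need <- c("v1PO4", "v1CO3", "CH2", "amideI")
  miss <- setdiff(need, names(bands))
  if (length(miss)) stop("band set missing: ", paste(miss, collapse = ", "))
  reasons <- character()
  get_m <- function(bn) {
    tryCatch(band_metrics(s, bands[[bn]]),
             error = function(e) {
               reasons[[bn]] <<- conditionMessage(e); NULL
             })
  }
  m958 <- get_m("v1PO4"); m1070 <- get_m("v1CO3")
  m1450 <- get_m("CH2"); m1656 <- get_m("amideI")
  val <- function(m, f) if (is.null(m)) NA_real_ else m[[f]]
  ratio <- function(num, den, nm) {
    a <- val(num, "A"); b <- val(den, "A")
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (b <= 0) { reasons[[nm]] <<- "denominator area <= 0"; return(NA_real_) }
    a / b
  }
  ci <- if (!is.null(m958) && !is.na(m958$FWHM) && m958$FWHM > 0)
    1 / m958$FWHM else { reasons[["CI"]] <- "FWHM undefined"; NA_real_ }

  cha <- NA_real_
  if (!is.null(bands$CH)) {
    b <- bands$CH
    if (min(s$wavenumbers) <= b$window_lo && max(s$wavenumbers) >= b$window_hi) {
      seg <- subtract_linear_baseline(s, b)
      tot <- trapz(s$wavenumbers, s$intensities)
      if (tot > 0) cha <- peak_area_eq1(seg) / tot
      else reasons[["cha_cont"]] <- "total spectrum area <= 0"
    } else {
      reasons[["cha_cont"]] <- "C-H window outside instrument range"
    }
  }
  out <- c(
    phosphate = val(m958, "I"),
    CI = ci,
    MMR = ratio(m958, m1656, "MMR"),
    carb_phos = ratio(m1070, m958, "carb_phos"),
    min_carb = ratio(m1070, m1450, "min_carb"),
    amide_I = val(m1656, "I"),
    cha_cont = cha)
  attr(out, "reasons") <- reasons
  out
}

#' Names of the six core markers
#' @export
marker_names <- function() {
  c("phosphate", "CI", "MMR", "carb_phos", "min_carb", "amide_I")
}
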