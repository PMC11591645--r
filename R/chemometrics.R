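#' Canonical diagnostic wavenumber regions
#'
#' The five windows used for region-wise PCA, each centered on one
#' diagnostic bone band, plus the full range.
#'
#' @return data.frame with region_id, lo, hi, assignment.
#' @export
wavenumber_regions <- function() {
  data.frame(
    region_id = c("I", "II", "III", "IV", "V"),
    lo = c(400, 920, 1200, 1410, 1550),
    hi = c(450, 990, 1320, 1490, 1730),
    assignment = c("nu2 PO4 (450)", "nu1 PO4 (958)", "amide III (1246)",
                   "CH2 deformation (1450)", "amide I (1656)"))
}

#' Build the sample-by-wavenumber matrix for a region
#'
#' One row per (replicate-averaged) sample spectrum, columns restricted to
#' the region. All spectra must share an identical pretreatment record and be
#' representable on a common grid; mixed provenance is an error.
#'
#' @param spectra list of pretreated [raman_spectrum], one per sample.
#' @param region either a region_id of [wavenumber_regions()], `"full"`, or a
#'   numeric `c(lo, hi)`.
#' @return list with `X` (matrix), `sample_ids`, `pmi_class`, `wavenumbers`,
#'   `pretreatment`.
#' @export
build_spectral_matrix <- function(spectra, region = "full") {
  if (!length(spectra)) stop("no spectra")
  prets <- lapply(spectra, function(s) s$metadata$pretreatment)
  if (any(vapply(prets, is.null, TRUE)))
    stop("provenance error: spectra lack a pretreatment record; run pretreat()")
  if (!all(vapply(prets[-1], identical, TRUE, prets[[1]])))
    stop("provenance error: spectra carry different pretreatment records")
  if (is.character(region)) {
    if (identical(region, "full")) {
      lo <- max(vapply(spectra, function(s) min(s$wavenumbers), 0))
      hi <- min(vapply(spectra, function(s) max(s$wavenumbers), 0))
    } else {
      wr <- wavenumber_regions()
      if (!region %in% wr$region_id) stop("unknown region: ", region)
      lo <- wr$lo[wr$region_id == region]; hi <- wr$hi[wr$region_id == region]
    }
  } else {
    lo <- region[1]; hi <- region[2]
  }
  for (s in spectra) {
    if (min(s$wavenumbers) > lo + 1e-9 || max(s$wavenumbers) < hi - 1e-9)
      stop(sprintf("range error: region [%g, %g] outside spectrum span [%g, %g]",
                   lo, hi, min(s$wavenumbers), max(s$wavenumbers)))
  }
  ax <- spectra[[1]]$wavenumbers
  shared <- all(vapply(spectra, function(s)
    length(s$wavenumbers) == length(ax) &&
      max(abs(s$wavenumbers - ax)) < 1e-9, TRUE))
  if (shared) {
    idx <- which(ax >= lo - 1e-9 & ax <= hi + 1e-9)
    grid <- ax[idx]
    X <- t(vapply(spectra, function(s) s$intensities[idx], numeric(length(idx))))
  } else {
    step <- min(vapply(spectra, function(s) stats::median(diff(s$wavenumbers)), 0))
    grid <- seq(lo, hi, by = step)
    X <- t(vapply(spectra, function(s)
      stats::approx(s$wavenumbers, s$intensities, xout = grid)$y,
      numeric(length(grid))))
  }
  list(X = X,
       sample_ids = vapply(spectra, `[[`, "", "sample_id"),
       pmi_class = vapply(spectra, `[[`, 0L, "pmi_class"),
       wavenumbers = grid,
       pretreatment = prets[[1]])
}

#' Principal component analysis of a spectral matrix
#'
#' Column-mean-centered PCA by singular value decomposition (no unit-variance
#' scaling: the channels share units and are already area-normalized).
#' Explained variance per component is taken over the total variance, not
#' just retained components. Component signs are fixed so each component's
#' largest-magnitude loading is positive, making repeated fits bit-identical
#' across linear-algebra backends.
#'
#' @param X samples x wavenumbers matrix, or the list from
#'   [build_spectral_matrix()].
#' @param n_components number of components to retain (default
#'   `min(dim) - 1` capped at 10).
#' @return object of class `raman_pca` with `scores`, `loadings`,
#'   `explained_variance_pct`, `center`, plus sample/channel metadata.
#' @export
fit_pca <- function(X, n_components = NULL) {
  meta <- NULL
  if (is.list(X) && !is.null(X$X)) { meta <- X; X <- X$X }
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("PCA needs at least 3 rows")
  if (max(apply(X, 2, stats::var)) <= 1e-300)
    stop("degenerate matrix: no variance to decompose")
  kmax <- min(nrow(X) - 1L, ncol(X))
  k <- min(n_components %||% min(kmax, 10L), kmax)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev_pct <- 100 * ev / sum(ev)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    if (load[which.max(abs(load[, i])), i] < 0) {
      load[, i] <- -load[, i]; scores[, i] <- -scores[, i]
    }
  }
  structure(list(scores = scores, loadings = load,
                 explained_variance_pct = ev_pct[seq_len(k)],
                 explained_variance_pct_all = ev_pct,
                 center = pc$center,
                 sample_ids = meta$sample_ids, pmi_class = meta$pmi_class,
                 wavenumbers = meta$wavenumbers,
                 pretreatment = meta$pretreatment),
            class = "raman_pca")
}

#' Correlation loadings
#'
#' Pearson correlation of each original channel with each score vector,
#' bounded in `[-1, 1]`; zero-variance channels get NA.
#'
#' @param model a fitted `raman_pca`.
#' @param X the training matrix (or [build_spectral_matrix()] list).
#' @return channels x components matrix of correlations.
#' @export
correlation_loadings <- function(model, X) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  out <- suppressWarnings(stats::cor(X, model$scores))
  out[sds <= 0, ] <- NA_real_
  out
}

#' Per-region PCA explained-variance report
#'
#' Fits a PCA in each diagnostic region and reports PC-1 / PC-2 explained
#' variance, the region-wise summary layout of the study.
#'
#' @param spectra list of pretreated sample spectra (one per sample).
#' @param regions data.frame as [wavenumber_regions()]; regions outside the
#'   spectra's span are skipped with a warning.
#' @return data.frame: region_id, lo, hi, assignment, pc1_pct, pc2_pct, n.
#' @export
region_report <- function(spectra, regions = wavenumber_regions()) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    m <- tryCatch(build_spectral_matrix(spectra,
                                        c(regions$lo[i], regions$hi[i])),
                  error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(m)) next
    fit <- fit_pca(m, n_components = 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = regions$region_id[i], lo = regions$lo[i], hi = regions$hi[i],
      assignment = regions$assignment[i],
      pc1_pct = fit$explained_variance_pct_all[1],
      pc2_pct = fit$explained_variance_pct_all[2],
      n = nrow(m$X))
  }
  do.call(rbind, rows)
}

#' Mean silhouette of PCA scores by class
#'
#' Summarizes how well the first score dimensions separate the PMI classes.
#'
#' @param model a `raman_pca`, or a scores matrix.
#' @param classes class labels (defaults to the model's `pmi_class`).
#' @param dims score dimensions used (default 1:2).
#' @export
score_silhouette <- function(model, classes = NULL, dims = 1:2) {
  scores <- if (inherits(model, "raman_pca")) model$scores else as.matrix(model)
  classes <- classes %||% model$pmi_class
  dims <- dims[dims <= ncol(scores)]
  cl <- as.integer(factor(classes))
  if (length(unique(cl)) < 2L) stop("need at least two classes")
  sil <- cluster::silhouette(cl, stats::dist(scores[, dims, drop = FALSE]))
  mean(sil[, "sil_width"])
}
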