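## Simulation studies: the reusable experiments behind the analysis scripts
## and the acceptance checks. Each one builds its generator configuration
## from stated study conditions, runs the pipeline's own functions, and
## returns summary numbers.

## Reduced-size handheld config for repeated simulation.
study_config <- function(n_per_class, classes = 1:4, replicates = 3L,
                         effects = class_effect_table(), seed = 1L,
                         instruments = NULL) {
  sizes <- stats::setNames(integer(5), as.character(1:5))
  sizes[as.character(classes)] <- n_per_class
  if (is.null(instruments))
    instruments <- list(handheld_profile(replicates_per_sample = replicates))
  synthetic_config(class_sizes = sizes, instruments = instruments,
                   effects = effects, seed = seed)
}

#' Type-I-error calibration of the pairwise contrasts
#'
#' Simulates datasets from the no-class-effect generator, runs the marker
#' pipeline and the pairwise contrasts, and reports the empirical rejection
#' rate at `alpha` per contrast. With a calibrated chain the rate equals
#' `alpha` up to Monte-Carlo error.
#'
#' @param n_datasets number of simulated datasets.
#' @param n_per_class samples per class.
#' @param classes classes simulated.
#' @param replicates replicate spectra per sample.
#' @param alpha test level.
#' @param seed master seed.
#' @param record pretreatment record.
#' @return list with `rejection_rate`, `n_tests`, `per_contrast`.
#' @export
null_contrast_calibration <- function(n_datasets = 2000, n_per_class = 15,
                                      classes = 1:4, replicates = 3L,
                                      alpha = 0.05, seed = 1L,
                                      record = pretreatment_record()) {
  hits <- 0L; total <- 0L
  per <- list()
  for (i in seq_len(n_datasets)) {
    cfg <- study_config(n_per_class, classes, replicates,
                        effects = null_effect_table(),
                        seed = derive_seed(seed, 17, i))
    ds <- generate_dataset(cfg)
    mm <- sample_marker_matrix(ds$spectra, record)
    st <- pairwise_class_contrasts(mm, reference_class = classes[1])
    rej <- st$p_value < alpha
    hits <- hits + sum(rej); total <- total + length(rej)
    per[[i]] <- data.frame(contrast = st$contrast, marker = st$marker,
                           reject = rej)
  }
  pc <- do.call(rbind, per)
  agg <- stats::aggregate(reject ~ contrast + marker, pc, mean)
  list(rejection_rate = hits / total, n_tests = total, per_contrast = agg)
}

#' Power and marker-recovery study for the class-1-vs-2 collagen contrast
#'
#' Simulates two-class datasets at the study group sizes under the default
#' class effects, and reports (i) how often the amide-I class-1-vs-2
#' contrast is significant at 0.05 and (ii) how far the simulation-averaged
#' per-class marker means sit from the generator's ground truth.
#'
#' @param n_datasets number of simulated datasets.
#' @param sizes sample sizes for classes 1 and 2.
#' @param replicates replicates per sample.
#' @param seed master seed.
#' @param record pretreatment record.
#' @return list with `power`, `max_rel_err` (worst six-marker relative error
#'   of class means vs ground truth), `class_means`, `ground_truth`.
#' @export
amide1_power_study <- function(n_datasets = 200, sizes = c(32L, 46L),
                               replicates = 3L, seed = 1L,
                               record = pretreatment_record()) {
  sig <- logical(n_datasets)
  sums <- NULL; counts <- NULL
  base_cfg <- NULL
  for (i in seq_len(n_datasets)) {
    cfg <- study_config(n_per_class = 1L, classes = 1:2,
                        replicates = replicates,
                        seed = derive_seed(seed, 23, i))
    cfg$class_sizes[c("1", "2")] <- sizes
    if (is.null(base_cfg)) base_cfg <- cfg
    ds <- generate_dataset(cfg)
    mm <- sample_marker_matrix(ds$spectra, record)
    st <- pairwise_class_contrasts(mm, reference_class = 1L)
    p12 <- st$p_value[st$marker == "amide_I" & st$class_b == 2L]
    sig[i] <- length(p12) == 1L && p12 < 0.05
    cm <- stats::aggregate(mm[marker_names()], list(pmi_class = mm$pmi_class),
                           mean, na.rm = TRUE)
    if (is.null(sums)) { sums <- cm; counts <- 1L }
    else { sums[marker_names()] <- sums[marker_names()] + cm[marker_names()]
           counts <- counts + 1L }
  }
  class_means <- sums
  class_means[marker_names()] <- class_means[marker_names()] / counts
  gt <- marker_ground_truth(base_cfg, base_cfg$instruments[[1]], record,
                            classes = 1:2)
  rel <- abs(as.matrix(class_means[marker_names()]) /
               as.matrix(gt[marker_names()]) - 1)
  list(power = mean(sig), max_rel_err = max(rel),
       class_means = class_means, ground_truth = gt)
}

#' Fluorescence QC exclusion rates at study scale
#'
#' Generates the full five-class handheld design and reports the fraction of
#' class-5 and class-1 replicates the QC gate excludes.
#'
#' @param threshold QC threshold.
#' @param replicates handheld replicates per sample.
#' @param seed master seed.
#' @return list with `class5_excluded`, `class1_excluded`, `by_class`.
#' @export
qc_exclusion_study <- function(threshold = 0.9, replicates = 5L, seed = 1L) {
  cfg <- synthetic_config(
    instruments = list(handheld_profile(replicates_per_sample = replicates)),
    seed = seed)
  ds <- generate_dataset(cfg)
  qc <- qc_gate(ds$spectra, threshold = threshold)
  by_class <- stats::aggregate(usable ~ pmi_class, qc$results, mean)
  by_class$excluded <- 1 - by_class$usable
  list(class5_excluded = by_class$excluded[by_class$pmi_class == 5],
       class1_excluded = by_class$excluded[by_class$pmi_class == 1],
       by_class = by_class)
}

## Effect table with the strong amplitude ladder confined to the bands of
## regions I (450), IV (1450) and V (1656); constant low fluorescence so no
## broad-background class signal leaks into other regions.
confined_effect_table <- function() {
  bn <- names(default_bone_bands())
  amp <- matrix(1, 5, length(bn), dimnames = list(NULL, bn))
  ladder <- c(1.00, 0.80, 0.65, 0.55, 0.45)
  amp[, "v2PO4"] <- ladder
  amp[, "CH2"] <- ladder
  amp[, "amideI"] <- ladder
  class_effect_table(
    amp_factor = amp,
    fwhm_shift = matrix(0, 5, length(bn), dimnames = list(NULL, bn)),
    fluor_scale = c(0.2, 0.2, 0.2, 0.2, 0.25),
    sample_cv = rep(0.08, 5))
}

#' Region-wise PCA behavior under constructed class effects
#'
#' With class effects confined to the bands of regions I, IV and V, those
#' regions should concentrate class variance in their leading components and
#' separate classes 1-4 in score space; the no-effect generator should show
#' no separation anywhere.
#'
#' @param mode `"confined"` or `"null"`.
#' @param n_per_class samples per class (classes 1-4).
#' @param replicates replicates per sample.
#' @param seed master seed.
#' @param record pretreatment record.
#' @return data.frame: region_id, pc1_pct, pc2_pct, pc12_pct, silhouette.
#' @export
region_variance_study <- function(mode = c("confined", "null"),
                                  n_per_class = 20L, replicates = 3L,
                                  seed = 1L,
                                  record = pretreatment_record()) {
  mode <- match.arg(mode)
  eff <- if (mode == "confined") confined_effect_table() else null_effect_table()
  cfg <- study_config(n_per_class, classes = 1:4, replicates = replicates,
                      effects = eff, seed = derive_seed(seed, 31, 1))
  ds <- generate_dataset(cfg)
  sm <- sample_mean_spectra(ds$spectra, record)
  wr <- wavenumber_regions()
  rows <- lapply(seq_len(nrow(wr)), function(i) {
    m <- build_spectral_matrix(sm, c(wr$lo[i], wr$hi[i]))
    fit <- fit_pca(m, 2L)
    data.frame(region_id = wr$region_id[i],
               pc1_pct = fit$explained_variance_pct_all[1],
               pc2_pct = fit$explained_variance_pct_all[2],
               pc12_pct = sum(fit$explained_variance_pct_all[1:2]),
               silhouette = score_silhouette(fit))
  })
  do.call(rbind, rows)
}

#' Cross-instrument consistency of marker class effects
#'
#' Renders the same simulated bone samples through both instrument models
#' and checks that the direction of each marker's class trend (slope of the
#' marker against PMI class 1-4) agrees between instruments.
#'
#' @param n_sims number of simulated datasets.
#' @param n_per_class samples per class.
#' @param replicates replicates per sample (both instruments).
#' @param seed master seed.
#' @param record pretreatment record.
#' @return list with `agreement` (fraction of simulations where all six
#'   marker trend signs agree) and `per_marker` sign-match rates.
#' @export
cross_instrument_sign_study <- function(n_sims = 100, n_per_class = 12L,
                                        replicates = 3L, seed = 1L,
                                        record = pretreatment_record()) {
  instruments <- list(handheld_profile(replicates_per_sample = replicates),
                      microscope_profile(replicates_per_sample = replicates))
  ok <- logical(n_sims)
  match_mat <- matrix(NA, n_sims, length(marker_names()),
                      dimnames = list(NULL, marker_names()))
  trend_sign <- function(mm, mk) {
    d <- mm[!is.na(mm[[mk]]), ]
    sign(stats::coef(stats::lm(d[[mk]] ~ d$pmi_class))[2])
  }
  for (i in seq_len(n_sims)) {
    cfg <- study_config(n_per_class, classes = 1:4, replicates = replicates,
                        seed = derive_seed(seed, 41, i),
                        instruments = instruments)
    ds <- generate_dataset(cfg)
    hh <- Filter(function(s) s$instrument == "handheld", ds$spectra)
    ms <- Filter(function(s) s$instrument == "microscope", ds$spectra)
    mm_h <- sample_marker_matrix(hh, record)
    mm_m <- sample_marker_matrix(ms, record)
    signs <- vapply(marker_names(), function(mk)
      trend_sign(mm_h, mk) == trend_sign(mm_m, mk), TRUE)
    match_mat[i, ] <- signs
    ok[i] <- all(signs)
  }
  list(agreement = mean(ok), per_marker = colMeans(match_mat))
}
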