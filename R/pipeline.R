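#' Write / read a dataset directory
#'
#' A dataset on disk is a directory of per-replicate spectrum files plus a
#' `sample_table.csv`.
#'
#' @param dataset list with `spectra` and `samples` as returned by
#'   [generate_dataset()].
#' @param dir target directory (created if missing).
#' @param format spectrum file format, `"csv"` or `"jcamp"`.
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "jdx"
  for (s in dataset$spectra) {
    fn <- sprintf("%s_%s_r%02d.%s", s$sample_id, s$instrument,
                  s$replicate_id, ext)
    write_spectrum(s, file.path(dir, fn), format)
  }
  write_sample_table(dataset$samples, file.path(dir, "sample_table.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  st_path <- file.path(dir, "sample_table.csv")
  if (!file.exists(st_path)) stop("no sample_table.csv in ", dir)
  samples <- read_sample_table(st_path)
  files <- list.files(dir, pattern = "\\.(csv|jdx|dx)$", full.names = TRUE)
  files <- files[basename(files) != "sample_table.csv"]
  spectra <- lapply(files, function(f) {
    s <- read_spectrum(f)
    m <- regmatches(basename(f),
                    regexec("^(.+)_([^_]+)_r(\\d+)\\.", basename(f)))[[1]]
    if (length(m) == 4L) {
      s$sample_id <- m[2]; s$instrument <- m[3]
      s$replicate_id <- as.integer(m[4])
      row <- samples[samples$sample_id == m[2] & samples$instrument == m[3], ]
      if (nrow(row)) s$pmi_class <- as.integer(row$pmi_class[1])
    }
    s
  })
  list(spectra = spectra, samples = samples)
}

#' Per-sample marker matrix from replicate spectra
#'
#' Groups replicate spectra by (sample, instrument), averages the usable
#' replicates, pretreats the mean spectrum and extracts the marker panel.
#' Markers are computed on the replicate-mean spectrum (the default
#' convention); `by = "replicate"` instead computes per replicate and then
#' averages the marker values.
#'
#' @param spectra list of [raman_spectrum] replicates (post-QC).
#' @param record a [pretreatment_record].
#' @param bands marker band definitions.
#' @param by `"sample"` (markers on replicate-mean spectra) or
#'   `"replicate"` (per-replicate markers, then averaged).
#' @return data.frame: sample_id, instrument, pmi_class, n_replicates + one
#'   column per marker (NA where non-assessable).
#' @export
sample_marker_matrix <- function(spectra, record = pretreatment_record(),
                                 bands = default_bands(),
                                 by = c("sample", "replicate")) {
  by <- match.arg(by)
  if (!length(spectra)) stop("no usable spectra")
  key <- paste(vapply(spectra, `[[`, "", "sample_id"),
               vapply(spectra, `[[`, "", "instrument"), sep = "||")
  groups <- split(seq_along(spectra), key)
  nmk <- 7L
  vals <- matrix(NA_real_, length(groups), nmk)
  meta <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    reps <- spectra[groups[[gi]]]
    if (by == "sample") {
      v <- marker_vector(pretreat(mean_spectrum(reps), record), bands)
    } else {
      pm <- vapply(reps, function(s)
        as.numeric(marker_vector(pretreat(s, record), bands)), numeric(nmk))
      v <- rowMeans(pm, na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
    }
    vals[gi, ] <- as.numeric(v)
    s1 <- reps[[1]]
    meta[[gi]] <- list(s1$sample_id, s1$instrument, s1$pmi_class, length(reps))
  }
  colnames(vals) <- c(marker_names(), "cha_cont")
  out <- data.frame(
    sample_id = vapply(meta, `[[`, "", 1L),
    instrument = vapply(meta, `[[`, "", 2L),
    pmi_class = vapply(meta, `[[`, 0L, 3L),
    n_replicates = vapply(meta, `[[`, 0L, 4L))
  out <- cbind(out, as.data.frame(vals))
  rownames(out) <- NULL
  out
}

## Pretreated replicate-mean spectrum per sample, for PCA input.
sample_mean_spectra <- function(spectra, record = pretreatment_record()) {
  key <- paste(vapply(spectra, `[[`, "", "sample_id"),
               vapply(spectra, `[[`, "", "instrument"), sep = "||")
  groups <- split(seq_along(spectra), key)
  lapply(groups, function(idx) pretreat(mean_spectrum(spectra[idx]), record))
}

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config], or NULL when reading from disk.
#' @param input_dir dataset directory (see [read_dataset]); overrides
#'   `synthetic` when given.
#' @param pretreatment a [pretreatment_record].
#' @param bands marker band definitions.
#' @param qc_threshold fluorescence-fraction gate threshold.
#' @param reference_class reference class for the contrasts.
#' @param stats_method contrast method, see [pairwise_class_contrasts].
#' @param p_adjust p-adjustment across markers.
#' @param regions PCA regions, as [wavenumber_regions()].
#' @param markers_by `"sample"` or `"replicate"`, see
#'   [sample_marker_matrix()].
#' @param out_dir output directory for CSV artifacts (NULL: nothing written).
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input_dir = NULL,
                       pretreatment = pretreatment_record(),
                       bands = default_bands(),
                       qc_threshold = 0.9,
                       reference_class = 1L,
                       stats_method = "lsd",
                       p_adjust = "none",
                       regions = wavenumber_regions(),
                       markers_by = "sample",
                       out_dir = NULL) {
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 pretreatment = pretreatment, bands = bands,
                 qc_threshold = qc_threshold,
                 reference_class = as.integer(reference_class),
                 stats_method = stats_method, p_adjust = p_adjust,
                 regions = regions, markers_by = markers_by,
                 out_dir = out_dir),
            class = "run_config")
}

config_fingerprint <- function(cfg) {
  js <- jsonlite::serializeJSON(cfg[setdiff(names(cfg), "out_dir")])
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' generate (or read) -> QC -> replicate means -> pretreat -> marker panel ->
#' pairwise class statistics -> region-wise PCA, with all tabular artifacts
#' written to `out_dir` when given. Identical config and seed give identical
#' outputs.
#'
#' @param cfg a [run_config].
#' @return (invisibly) list with `qc`, `markers`, `stats`, `pca_regions`,
#'   `pca_scores`, `sample_spectra`, `config_hash`, per instrument.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_fingerprint(cfg)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"), msg))
  }
  dataset <- if (!is.null(cfg$input_dir)) {
    say("reading dataset from %s", cfg$input_dir)
    read_dataset(cfg$input_dir)
  } else {
    say("generating synthetic dataset (seed %d)", cfg$synthetic$seed)
    generate_dataset(cfg$synthetic)
  }
  say("%d replicate spectra, %d sample rows",
      length(dataset$spectra), nrow(dataset$samples))

  instruments <- unique(vapply(dataset$spectra, `[[`, "", "instrument"))
  qc_all <- list(); markers_all <- list(); stats_all <- list()
  regions_all <- list(); scores_all <- list(); spectra_by_instr <- list()

  for (instr in instruments) {
    sp <- Filter(function(s) identical(s$instrument, instr), dataset$spectra)
    qc <- qc_gate(sp, threshold = cfg$qc_threshold)
    say("%s: QC excluded %d/%d replicates", instr,
        sum(!qc$results$usable), nrow(qc$results))
    qc_all[[instr]] <- qc$results
    if (!length(qc$usable)) next

    mm <- sample_marker_matrix(qc$usable, cfg$pretreatment, cfg$bands,
                               by = cfg$markers_by)
    markers_all[[instr]] <- mm
    st <- tryCatch(
      pairwise_class_contrasts(mm, cfg$reference_class,
                               method = cfg$stats_method,
                               p_adjust = cfg$p_adjust),
      error = function(e) { say("%s: stats skipped (%s)", instr,
                                conditionMessage(e)); NULL })
    if (!is.null(st)) stats_all[[instr]] <- cbind(instrument = instr, st)

    sm <- sample_mean_spectra(qc$usable, cfg$pretreatment)
    spectra_by_instr[[instr]] <- sm
    rr <- suppressWarnings(region_report(sm, cfg$regions))
    if (!is.null(rr)) regions_all[[instr]] <- cbind(instrument = instr, rr)
    sc <- list()
    for (i in seq_len(nrow(cfg$regions))) {
      m <- tryCatch(build_spectral_matrix(
        sm, c(cfg$regions$lo[i], cfg$regions$hi[i])),
        error = function(e) NULL)
      if (is.null(m)) next
      fit <- fit_pca(m, 2L)
      sc[[length(sc) + 1L]] <- data.frame(
        instrument = instr, region_id = cfg$regions$region_id[i],
        sample_id = fit$sample_ids, pmi_class = fit$pmi_class,
        PC1 = fit$scores[, 1],
        PC2 = if (ncol(fit$scores) > 1) fit$scores[, 2] else NA_real_)
    }
    if (length(sc)) scores_all[[instr]] <- do.call(rbind, sc)
  }

  out <- list(qc = do.call(rbind, unname(qc_all)),
              markers = do.call(rbind, unname(markers_all)),
              stats = do.call(rbind, unname(stats_all)),
              pca_regions = do.call(rbind, unname(regions_all)),
              pca_scores = do.call(rbind, unname(scores_all)),
              sample_spectra = spectra_by_instr,
              samples = dataset$samples,
              config_hash = hash, log = log_lines)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- sprintf("# boneraman %s config %s",
                   as.character(utils::packageVersion("boneraman")), hash)
    wcsv <- function(df, name) {
      if (is.null(df)) return()
      path <- file.path(cfg$out_dir, name)
      con <- file(path, "w")
      writeLines(hdr, con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    wcsv(out$qc, "qc.csv")
    wcsv(out$markers, "markers.csv")
    wcsv(out$stats, "stats.csv")
    wcsv(out$pca_regions, "pca_regions.csv")
    wcsv(out$pca_scores, "pca_scores.csv")
    jsonlite::write_json(
      list(config_hash = hash, qc_threshold = cfg$qc_threshold,
           reference_class = cfg$reference_class,
           stats_method = cfg$stats_method,
           pretreatment = unclass(cfg$pretreatment),
           seed = if (is.null(cfg$input_dir)) cfg$synthetic$seed else NA,
           class_sizes = if (is.null(cfg$input_dir))
             as.list(cfg$synthetic$class_sizes) else NULL),
      file.path(cfg$out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
    writeLines(out$log, file.path(cfg$out_dir, "log.txt"))
  }
  invisible(out)
}
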