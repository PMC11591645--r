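#!/usr/bin/env Rscript
## Marker panel and class statistics: the six bone-quality markers per
## sample, then class-1-versus-k contrasts with star coding, shaped like
## the study's marker tables.

source("analysis/00_config.R")

res <- run_pipeline(run_config(synthetic = study_dataset_config(),
                               out_dir = RESULTS_DIR))

determinations <- c(phosphate = "I958", CI = "1/FWHM958",
                    MMR = "A958/A1656", carb_phos = "A1070/A958",
                    min_carb = "A1070/A1450", amide_I = "I1656")

st <- res$stats
st$determination <- determinations[st$marker]
st$cell <- sprintf("%.4g %s", st$p_value, st$significance)
wide <- reshape(st[, c("instrument", "marker", "determination",
                       "contrast", "cell")],
                idvar = c("instrument", "marker", "determination"),
                timevar = "contrast", direction = "wide")
names(wide) <- sub("^cell\\.", "", names(wide))
write.csv(wide, file.path(RESULTS_DIR, "marker_contrast_table.csv"),
          row.names = FALSE)

cat("marker contrast table (per instrument, p-value + stars):\n")
print(wide, row.names = FALSE)

n_sig <- sum(st$significance != "ns")
cat(sprintf("\nfound: %d of %d contrasts significant at 0.05;\n",
            n_sig, nrow(st)))
cat("under the default diagenesis trends every marker separates class 1\n")
cat("from class 2 on both instruments except where noted above.\n")
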