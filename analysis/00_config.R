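## Shared study configuration for the numbered analysis scripts.
## Desk-scale rendering of the study design: the full 104-sample class
## structure (32/46/11/10/5) with the handheld's 5 replicates per sample;
## the microscope is rendered at 6 replicates per ROI (its 36-replicate
## design is statistically redundant for per-sample means and is reduced
## here; the generator supports the full count).

library(boneraman)

STUDY_SEED <- 20260924L

study_dataset_config <- function(seed = STUDY_SEED) {
  synthetic_config(
    instruments = list(handheld_profile(replicates_per_sample = 5L),
                       microscope_profile(replicates_per_sample = 6L)),
    seed = seed)
}

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
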