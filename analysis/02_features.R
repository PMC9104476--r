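#!/usr/bin/env Rscript
# Step 2: preprocess every recording and extract the 46-feature library.
#
# Each recording is band-pass filtered (Kaiser FIR, 20-400 Hz, zero phase),
# the swallow burst is localized on a 1000 ms moving-RMS envelope, and the
# 1500-sample burst window plus the last-1.5 s baseline window are
# featurized per channel (channel mean). Reads the cohort written by
# 01_simulate.R back from disk, so the CSV readers are exercised too.

library(swallowEMG)

cohort_dir <- "results/cohort"
meta <- read.csv(file.path(cohort_dir, "metadata.csv"))
recordings <- lapply(seq_len(nrow(meta)), function(i)
  read_recording(file.path(cohort_dir, meta$file[i]),
                 subject_id = meta$subject[i], task = meta$task[i],
                 volume_mL = meta$volume_mL[i]))
cohort <- list(recordings = recordings,
               metadata = meta[c("recording", "subject", "task", "volume_mL")])

features <- extract_cohort_features(cohort)
write.csv(features, "results/feature_matrix.csv", row.names = FALSE)

cat("feature matrix:", nrow(features), "observations x",
    ncol(features) - 5, "features\n")
cat("rows per kind:", paste(names(table(features$kind)),
                            table(features$kind), collapse = ", "), "\n")
# burst windows should dwarf baseline windows in energy
med <- tapply(features$RMS, features$kind, median)
cat(sprintf("median RMS: burst %.1f uV vs baseline %.1f uV\n",
            med[["burst"]], med[["baseline"]]))
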