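#!/usr/bin/env Rscript
# QC-filter and normalise every sample of the simulated cohort.
# Run from the repository root after 01_simulate.R.
source("analysis/00_config.R")

dirs <- list.dirs(file.path(RESULTS, "cohort"), recursive = FALSE)
samples <- lapply(dirs, read_sample_mtx)
samples <- qc_filter_samples(samples, min_malignant_cells = 200)

summary <- do.call(rbind, lapply(samples, function(m) {
  before <- dim(m)
  m2 <- study_qc(m)
  data.frame(sample_id = m$sample_id,
             genes_in = before[1], cells_in = before[2],
             genes_out = nrow(m2$counts), cells_out = ncol(m2$counts))
}))
write.table(summary, file.path(RESULTS, "qc_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary, row.names = FALSE)
cat("normalized layers are recomputed on the fly by the NMF driver\n")
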