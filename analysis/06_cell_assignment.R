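#!/usr/bin/env Rscript
# Score every cell against every meta-program and assign arg-max labels
# under the 25-gene conservation and 5% prevalence rules; check labels
# against the planted ground truth.
# Run from the repository root after 05_meta_programs.R.
source("analysis/00_config.R")

tab <- read.delim(file.path(RESULTS, "robust_programs.tsv"))
robust <- program_set(table_to_programs(tab))
mps <- cluster_all(robust)$mps   # rebuilt to recover member weights

dirs <- list.dirs(file.path(RESULTS, "cohort"), recursive = FALSE)
samples <- lapply(dirs, function(d) study_qc(read_sample_mtx(d)))

assignments <- lapply(samples, function(m)
  assign_cells(score_cells(m, mps, min_genes_conserved = 25,
                           seed = MASTER_SEED + 2L),
               min_prevalence = 0.05, sample_id = m$sample_id))

labels <- do.call(rbind, lapply(assignments, function(a)
  data.frame(cell_id = names(a$labels), sample_id = a$sample_id,
             mp_label = unname(a$labels))))
write.table(labels, file.path(RESULTS, "cell_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(RESULTS, "cohort", "truth.tsv"))
merged <- merge(labels, truth, by = c("sample_id", "cell_id"))
cat("label x planted-truth contingency (single-program cells):\n")
single <- merged[!grepl(",", merged$active_programs), ]
print(table(label = single$mp_label, truth = single$active_programs,
            useNA = "ifany"))
for (a in assignments)
  cat(sprintf("%s: retained %s; %d unresolved\n", a$sample_id,
              paste(sprintf("%s=%.0f%%", names(a$prevalence),
                            100 * a$prevalence), collapse = " "),
              sum(a$labels == "unresolved")))
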