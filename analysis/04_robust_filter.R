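#!/usr/bin/env Rscript
# Apply the three robustness criteria (cross-rank recurrence, cross-sample
# recurrence, within-sample non-redundancy) to the per-sample programs.
# Run from the repository root after 03_nmf_programs.R.
source("analysis/00_config.R")

tab <- read.delim(file.path(RESULTS, "programs.tsv"))
pool <- program_set(table_to_programs(tab))
robust <- select_robust(pool)

audit <- attr(robust, "audit")
write.table(audit, file.path(RESULTS, "robust_audit.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(programs_to_table(robust$programs),
            file.path(RESULTS, "robust_programs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d / %d programs pass intra-sample recurrence\n",
            sum(audit$pass_intra), nrow(audit)))
cat(sprintf("%d / %d programs pass inter-sample recurrence\n",
            sum(audit$pass_inter), nrow(audit)))
cat(sprintf("%d robust programs retained after deduplication\n",
            length(robust)))
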