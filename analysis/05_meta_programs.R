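#!/usr/bin/env Rscript
# Cluster robust programs by shared genes (founder + accretion) into
# 50-gene meta-programs and compare them with the planted truth.
# Run from the repository root after 04_robust_filter.R.
source("analysis/00_config.R")

tab <- read.delim(file.path(RESULTS, "robust_programs.tsv"))
robust <- program_set(table_to_programs(tab))
out <- cluster_all(robust)

write_gmt(setNames(lapply(out$mps, `[[`, "genes"),
                   vapply(out$mps, `[[`, "", "mp_id")),
          file.path(RESULTS, "meta_programs.gmt"))
membership <- do.call(rbind, lapply(out$mps, function(mp)
  data.frame(mp_id = mp$mp_id,
             member = vapply(mp$members, function(p)
               sprintf("%s|K%d|f%d", p$sample_id, p$rank_k,
                       p$factor_index), ""))))
write.table(membership, file.path(RESULTS, "mp_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d meta-programs from %d robust programs (%d unassigned)\n",
            length(out$mps), length(robust), length(out$unassigned)))
for (mp in out$mps) {
  ov <- sapply(1:3, function(i) length(intersect(mp$genes, plant_genes(i))))
  cat(sprintf("  %s: %d members, best plant overlap %d/50 (%s)\n",
              mp$mp_id, length(mp$members), max(ov),
              ifelse(max(ov) >= 35, paste0("matches P", which.max(ov)),
                     "no plant")))
}
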