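#!/usr/bin/env Rscript
# Generate the synthetic study cohort and spatial slide with ground truth.
# Run from the repository root: Rscript analysis/01_simulate.R
source("analysis/00_config.R")

sim <- simulate_cohort(study_cohort)
write_cohort(sim, file.path(RESULTS, "cohort"))
cat(sprintf("cohort: %d samples x %d genes x %d cells; %d cells carry a planted program\n",
            length(sim$samples), study_cohort$n_genes,
            study_cohort$cells_per_sample,
            sum(sim$truth$active_programs != "")))

sp <- simulate_spatial(study_spatial)
write_spot_grid(sp$grid, file.path(RESULTS, "spot_grid.tsv"))
write.table(sp$truth$association,
            file.path(RESULTS, "spatial_truth_association.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("slide: %d spots (%d tumour), cell types: %s\n",
            nrow(sp$grid$spots), sum(sp$grid$is_tumour),
            paste(colnames(sp$grid$weights), collapse = ", ")))
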