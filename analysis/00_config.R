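# Shared configuration for the analysis drivers: the study conditions used
# throughout (8-sample cohort, three shared 50-gene planted programs at
# effect size 8 / activity 0.2, 300 genes x 300 cells per sample; one
# 32 x 32 slide with a planted fibroblast association and a null pair).
# Every driver sources this file and works under results/.

library(consensusMP)

MASTER_SEED <- 2026L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

plant_genes <- function(i) sprintf("PG%d_%02d", i, 1:50)

study_plants <- lapply(1:3, function(i)
  planted_program(paste0("P", i), plant_genes(i),
                  activity_rate = 0.2, effect_size = 8))

study_cohort <- cohort_config(
  n_samples = 8, n_genes = 300, cells_per_sample = 300,
  shared_programs = study_plants, baseline_mean = 0.5, dispersion = 0.5,
  seed = MASTER_SEED)

study_spatial <- spatial_config(
  n_rows = 32, n_cols = 32,
  association = list(
    list(mp_id = "MP_planted", cell_type = "fibroblast", slope = 6),
    list(mp_id = "MP_null", cell_type = "T_cell", slope = 0)),
  seed = MASTER_SEED + 1L)

# QC thresholds scaled to the simulated depth (300 genes, ~150 counts per
# cell); the droplet-scale defaults would empty these small matrices.
study_qc <- function(m)
  qc_filter_genes(qc_filter_cells(m, min_features = 30, max_counts = 1e5),
                  min_cells = 10)
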