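# consensusMP

Consensus-NMF meta-program discovery and tumour-neighbourhood analysis
for single-cell and spatial transcriptomics.

Malignant cells inside one tumour occupy recurrent expression states —
cycling, stress, secretory programs — that reappear across patients.
`consensusMP` implements the standard consensus non-negative matrix
factorisation route to charting them, for computational biologists who
want the whole chain as tested, reusable functions rather than a
one-off script:

1. per-sample NMF of the variance-stabilised expression matrix over a
   range of ranks, each factor summarised by its top 50 genes;
2. robustness filtering of those programs (cross-rank recurrence,
   cross-sample recurrence, within-sample non-redundancy);
3. Jaccard/overlap-based founder clustering of the robust programs into
   **meta-programs (MPs)** — consensus 50-gene signatures;
4. per-cell MP scoring (bin-matched control module scores) and arg-max
   assignment with conservation and prevalence safeguards;
5. for spatial slides: a **tumour neighbourhood score** relating each
   tumour spot's MP score to the cell-type composition of its adjacent
   spots.

A synthetic-data generator plants known co-expression programs in
negative-binomial counts and known MP/cell-type spatial associations in
Dirichlet deconvolution weights, so every stage is validated by
parameter recovery against ground truth.

## The model in brief

Per sample, the normalised matrix `A` (genes × cells,
`log2(1 + CPM/10)` centred per gene and clipped at 0) is factorised as
`A ≈ W H` with `W, H ≥ 0` for each rank `K = 4…9`; each factor
contributes a program of its 50 top-weighted genes (39 programs per
sample). A program is *robust* if it shares ≥ 35/50 genes with a
different-rank program of its sample and ≥ 10/50 with a program of
another sample; redundant same-sample survivors (> 15/50 shared) are
dropped. Robust programs are clustered by shared genes: a founder needs
more than 5 supporters at ≥ 8 shared genes; members accrete at ≥ 10
genes against the evolving signature, which is recompleted to 50 genes
(frequency, then mean NMF weight, then id) after every admission.

A cell's score for signature `S` is
`mean(expr[S]) − mean(expr[ctrl(S)])` on centred log expression, with
controls drawn per signature gene from its average-expression bin. Cells
take the arg-max MP; MPs labelling < 5% of a sample's cells are dropped
and their cells are `"unresolved"`. On a spot lattice, the
neighbourhood score of cell type `c` at tumour spot `s` is
`N_c(s) = Σ_{s′ ∈ adj8(s)} w_c(s′)`, and MP–microenvironment
association is the Pearson correlation between MP scores and `N_c`
across tumour spots pooled over slides.

## Worked example

Plant three shared 50-gene programs in an 8-sample cohort (effect size
8, 20% of cells active), plus a slide where fibroblast weights track one
MP's activity, and run the whole pipeline:

```r
library(consensusMP)

plants <- lapply(1:3, function(i)
  planted_program(paste0("P", i), sprintf("PG%d_%02d", i, 1:50),
                  activity_rate = 0.2, effect_size = 8))
cfg <- run_config(
  cohort = cohort_config(n_samples = 8, n_genes = 300,
                         cells_per_sample = 300,
                         shared_programs = plants),
  spatial = spatial_config(
    n_rows = 32, n_cols = 32,
    association = list(
      list(mp_id = "MP_planted", cell_type = "fibroblast", slope = 6),
      list(mp_id = "MP_null",    cell_type = "T_cell",     slope = 0))),
  min_features = 30, max_counts = 1e5, min_cells = 10,  # synthetic depth
  seed = 2026)
res <- run_pipeline(cfg)

length(res$programs)   # 312  = 8 samples x (4+5+...+9) programs
length(res$robust)     # 56   robust programs after the three criteria
length(res$mps)        # 4    meta-programs
sapply(res$mps, function(mp) max(sapply(1:3, function(i)
  length(intersect(mp$genes, sprintf("PG%d_%02d", i, 1:50))))))
# 0 50 50 50   <- three MPs reproduce the three plants gene-for-gene;
#               the fourth collects the shared background factor
res$assignments[[1]]
# <cell_assignment> S01: 300 cells, 4 retained MPs, 0 unresolved
round(res$spatial$correlation$pooled, 3)
#            fibroblast T_cell B_cell myeloid endothelial
# MP_planted      0.571 -0.329 -0.350  -0.331      -0.335
# MP_null         0.068 -0.018 -0.023  -0.196      -0.073
```

The planted MP/fibroblast pair stands out (r = 0.57 across 1024 tumour
spots); the null pair stays near zero. The compositional constraint of
Dirichlet weights makes the planted cell type's gains show up as mild
negative correlations for the others.

The same analysis, stage by stage with intermediate tables under
`results/`, is scripted in `analysis/01_simulate.R` …
`analysis/07_spatial.R` (run each from the repository root).

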