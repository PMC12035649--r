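---
title: "Meta-program discovery and tumour-neighbourhood analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-program discovery and tumour-neighbourhood analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusMP)
```

# The problem

Malignant cells within one tumour occupy a spectrum of expression states —
cycling, stress-response, secretory, and so on — and the same states recur
across patients. A standard way to chart this intra-tumoural heterogeneity
in single-cell RNA-seq is consensus non-negative matrix factorisation:
factorise each tumour sample separately, keep the factors that recur, and
cluster their gene signatures across samples into *meta-programs* (MPs) —
consensus 50-gene signatures of recurrent malignant cell states. A second
question is spatial: which microenvironment cell types sit *next to* the
tumour cells expressing a given MP. This package implements both the
discovery pipeline and the spatial neighbourhood statistic, together with
a synthetic-data generator that plants known programs and associations so
every stage can be validated by parameter recovery.

# The discovery procedure

1. **QC** (`qc_filter_cells`, `qc_filter_genes`, `qc_filter_samples`).
   Cells are kept with strictly more than 300 detected genes and strictly
   fewer than 7500 total counts; genes must be detected in at least 100
   cells; samples need at least 200 malignant cells. The boundary
   behaviour is deliberate: both cell-level inequalities are strict, the
   gene and sample thresholds are inclusive. Malignant-cell identity is an
   *input* (a flag per cell) — annotation is upstream of this package.

2. **Normalisation** (`normalize_for_nmf`). Counts become
   `log2(1 + CPM/10)` per cell, are centred per gene across cells, and
   negatives are clipped to zero. Centring makes a factor describe
   *relative* up-regulation; clipping restores the non-negativity NMF
   needs. A centred-then-clipped matrix is the standard input for
   intra-tumoural heterogeneity NMF work, and the clipped zeros carry no
   information beyond "not above average".

3. **Per-sample NMF** (`factorize`, `extract_programs`). Each sample is
   factorised at every rank K in 4–9 with multiplicative Frobenius
   updates (at most 500 iterations, relative-error tolerance `1e-4`,
   convergence checked every 10 iterations) from a deterministic NNDSVDa
   initialisation. Determinism matters more here than squeezing out the
   last fraction of reconstruction error: identical inputs must give
   identical programs for the downstream overlap filters to be
   reproducible, so we use an SVD-seeded start rather than random
   restarts (restarts are configurable but default to one). Each factor
   becomes a program: its 50 top-weighted genes, ties broken by gene id.
   The program count per sample is therefore exactly 4+5+…+9 = 39
   whatever the data.

4. **Robustness filter** (`select_robust`). A program is kept when (1)
   some program of a *different* K in the same sample shares ≥ 35 of its
   50 genes (70%), and (2) some program of a *different sample* shares
   ≥ 10 genes (20%). Survivors are then de-duplicated within each sample:
   processed in decreasing order of their maximal cross-sample overlap, a
   program sharing more than 15 genes (30%) with an already-retained
   same-sample program is dropped. The percentages are interpreted
   against the fixed program size of 50; criteria 1–2 are inclusive
   (≥), criterion 3 exclusive (> 15 drops).

   One subtlety: criterion 3 removes exactly the cross-rank twins that
   criterion 1 needs as evidence, so re-filtering the *survivors* naively
   would empty the set. The returned program set therefore carries its
   candidate pool as an `evidence` attribute, and re-application
   re-evaluates the recurrence criteria against that provenance. This
   makes the filter idempotent, which is also the honest reading of the
   criteria — they are statements about the full pool a program came
   from, not about whichever subset happens to be in hand.

5. **MP clustering** (`cluster_all`). Founder selection: a program
   qualifies when more than 5 other programs share at least 8 genes with
   it; the most-supported program founds a cluster (ties: larger mean
   overlap with supporters, then deterministic sample/rank order). The
   founder and its best partner seed the cluster; the MP signature is
   built by `complete_mp`: genes ranked by member frequency, then mean
   NMF weight, then id, top 50 kept — so the members' common genes come
   first and the signature is completed by the strongest remainder.
   Accretion then repeatedly admits the pool program sharing the most
   genes with the *current* signature (minimum 10), recomputing the
   signature after every admission. Clusters are built until no founder
   qualifies; admitted programs leave the pool, so MP memberships are
   disjoint and leftovers are reported as unassigned rather than forced
   into a cluster.

6. **Cell scoring and assignment** (`signature_score`, `score_cells`,
   `assign_cells`, `mp_module_scores`). The score of a signature in a
   cell is the mean centred log-expression of the signature genes minus
   the mean over bin-matched controls: genes are cut into
   equal-occupancy average-expression bins (30 for assignment scoring,
   24 for module scores), and each signature gene contributes up to 100
   control genes drawn without replacement from its own bin. An MP is
   scored in a sample only if at least 25 of its 50 genes are present.
   Cells take the arg-max MP; an MP labelling fewer than 5% of the
   sample's cells is dropped in a single pass and its cells become
   `"unresolved"` (not reassigned to their second choice). Post-drop
   prevalences are recorded so residual sub-5% labels are visible.

7. **Spatial neighbourhood** (`neighbourhood`, `neighbourhood_score`,
   `mp_tme_correlation`). Spots live on a square lattice; the
   neighbourhood of a spot is the 8 adjacent positions (Moore
   neighbourhood), truncated at grid edges with no renormalisation. The
   tumour neighbourhood score of a cell type at a tumour spot is the sum
   of that type's deconvolution weights over the neighbours; the same sum
   over per-spot signature scores gives neighbourhood signature scores.
   MP–microenvironment association is the Pearson correlation between MP
   scores at tumour spots and neighbourhood scores, pooled across slides
   without per-slide standardisation (per-slide matrices are also
   returned). A 6-neighbour hexagonal mode (`mode = "hex"`) is available
   for real Visium array coordinates, where physical adjacency is
   hexagonal.

# The synthetic generator

`simulate_cohort` plants binary-activity co-expression programs in
negative-binomial counts: gene g in cell j has mean `baseline_mean`
multiplied by the `effect_size` of every program active in j that
contains g, with variance `mu + dispersion * mu^2`. Negative-binomial
noise (not Poisson) reflects the overdispersion of droplet data;
binary per-cell activity (a cell either runs the program or not) keeps
ground-truth recovery checks unambiguous in a way graded activity would
not. Shared programs must have disjoint gene sets so that "which plant
did this MP recover" has a unique answer.

`simulate_spatial` builds a square grid of spots. Each MP named in the
association list receives a spatially smooth activity field in [0, 1]
(uniform noise smoothed by a few passes of 8-neighbour averaging —
smoothness is essential, since the neighbourhood statistic correlates a
spot's MP score with its *neighbours'* composition). Per-spot cell-type
weights are a Dirichlet draw whose concentration for an associated cell
type is shifted by `slope ×` the local MP activity, so `slope > 0`
plants a recoverable positive association and `slope = 0` a null pair.
Optionally, per-spot expression is generated with MP genes boosted by
the activity, so spots can be scored and labelled like cells.

## Study conditions and problem sizes

The default conditions used by the tests, the analysis drivers and the
acceptance script are: 8 samples × 300 genes × 300 cells, three shared
50-gene planted programs at effect size 8 and activity rate 0.2,
baseline mean 0.5 counts/gene/cell, dispersion 0.5; slides of 32 × 32
spots (1024 tumour spots) with five cell types, one planted association
(slope 6) and one null pair. Program-counting checks use a 44-sample
cohort at 300 genes × 200 cells. Effect size 8 with ~20% active cells is
a strong, cleanly separable program — the regime in which consensus NMF
is expected to work; the recovery tests ask whether the *pipeline*
loses it, not whether NMF can detect arbitrarily weak signals.

## What the generator does not emulate

Real droplet data have heavy-tailed per-gene baseline expression,
ambient RNA, doublets, batch effects, and continuous program activity;
real Visium slides have hexagonal geometry, uneven spot depth and
segmentation artefacts. None of these are simulated (per-gene baselines
are flat by default). Passing the recovery tests therefore shows the
pipeline's logic is correct and its thresholds behave as specified on
well-posed input — not that the method is robust to every real-data
pathology. One consequence worth knowing: with a flat baseline the
planted genes are the only high-mean genes, so bin-matched controls for
a planted signature are drawn largely from the signature itself and
module scores shrink towards zero. This is a property of expression-bin
control matching on small flat universes, not a bug; scoring tests that
need realistic bins use heterogeneous baselines built in the test.

# Numerical and design choices

* **QC boundaries**: strict `>`/`<` for the cell filters, inclusive for
  gene/sample filters, as stated above; values at 300 detected genes or
  7500 counts are removed.
* **NMF**: multiplicative updates with `eps = 1e-10` guards against
  division by zero; NNDSVDa replaces zero initial entries with the
  matrix mean to avoid the zero-locking of multiplicative updates.
* **Tie-breaks** are deterministic everywhere: gene ids for top-gene
  selection and signature completion; first column for arg-max
  assignment ties; sample id, then rank, then factor index for program
  ordering in founder selection, accretion and deduplication.
* **Founder rule**: "more than 5 supporters at ≥ 8 shared genes" — both
  numbers are exposed as parameters. Note a 6-member program family
  gives each member only 5 supporters and founds nothing; recurrent
  states need ≥ 7 members at these defaults.
* **Dropped-MP cells** become `"unresolved"` rather than taking their
  second-best MP, and the prevalence pass runs once, not to a fixpoint.
* **Degenerate inputs** fail loudly: empty samples after QC, cells with
  zero counts (named), signatures with no genes in the matrix,
  single-sample pools for the inter-sample criterion, grids smaller than
  3 × 3, zero-variance series in correlations (flagged `NA`, never a
  silent 0).
* **Seeds**: a single master seed derives per-stage seeds; the NMF
  initialisation is deterministic, so the only seed-sensitive stages are
  simulation and control-gene draws.

# Known limitations

* The founder/accretion clustering is greedy and order-dependent by
  construction; the deterministic tie-breaks make it reproducible, but a
  different priority rule could yield different (equally valid) cluster
  boundaries on borderline pools.
* Percent thresholds assume the fixed 50-gene program size; changing
  `genes_per_program` rescales them implicitly (35/10/15 stay gene
  counts, not percentages).
* The spatial statistic assumes one square lattice per slide; hex mode
  covers Visium adjacency but no other array geometry.
* No doublet handling, batch integration, deconvolution or pathway
  enrichment — those belong to upstream/downstream tools.
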