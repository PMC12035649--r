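# Shared fixture builders. Everything is generated in code; no files.

# gene universe helpers
gene_ids <- function(n, prefix = "g") sprintf("%s%04d", prefix, seq_len(n))
plant_genes <- function(i, n = 50) sprintf("PG%d_%02d", i, seq_len(n))

# an nmf_program with weights descending from n to 1
make_prog <- function(sample_id, rank_k, factor_index, genes) {
  nmf_program(sample_id, rank_k, factor_index, genes,
              weights = rev(seq_along(genes)))
}

# a program whose gene list is `shared` plus unique fillers up to `size`
make_prog_around <- function(sample_id, rank_k, factor_index, shared,
                             size = 50, filler_prefix = "x") {
  fill <- sprintf("%s_%s_K%d_f%d_%02d", filler_prefix, sample_id, rank_k,
                  factor_index, seq_len(size - length(shared)))
  make_prog(sample_id, rank_k, factor_index, c(shared, fill))
}

# stable (sample, rank, factor) identity for comparing programs
pkey <- function(p)
  sprintf("%s|K%d|f%d", p$sample_id, p$rank_k, p$factor_index)

# wrap a gene list as a one-member meta_program
mk_mp <- function(id, genes)
  meta_program(id, genes, members = list(make_prog("x", 4, 0, genes)),
               founder = make_prog("x", 4, 0, genes), size = length(genes))

# small counts matrix with named dims
make_counts <- function(n_genes, n_cells, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes,
              dimnames = list(gene_ids(n_genes), sprintf("c%03d", seq_len(n_cells))))
  m
}

# standard 3-plant / 8-sample study cohort configuration
study_cohort_config <- function(seed, n_samples = 8, cells = 300) {
  plants <- lapply(1:3, function(i)
    planted_program(paste0("P", i), plant_genes(i),
                    activity_rate = 0.2, effect_size = 8))
  cohort_config(n_samples = n_samples, n_genes = 300,
                cells_per_sample = cells, shared_programs = plants,
                seed = seed)
}

# QC thresholds scaled to the synthetic depth (300 genes, ~150 counts/cell)
synthetic_qc <- function(m)
  qc_filter_genes(qc_filter_cells(m, min_features = 30, max_counts = 1e5),
                  min_cells = 10)

# cohort -> list of meta_programs, the pipeline's discovery stages only
discover_mps <- function(sim, k_range = 4:9) {
  samples <- lapply(sim$samples, function(m)
    normalize_for_nmf(synthetic_qc(m)))
  progs <- unlist(lapply(samples, extract_programs, k_range = k_range),
                  recursive = FALSE)
  cluster_all(select_robust(program_set(progs)))
}

# how many of the 3 plants are matched by distinct MPs at >= min_genes
n_plants_recovered <- function(mps, min_genes = 35) {
  if (length(mps) == 0L) return(0L)
  ov <- sapply(1:3, function(i) sapply(mps, function(mp)
    length(intersect(mp$genes, plant_genes(i)))))
  ov <- matrix(ov, nrow = length(mps))
  hit <- 0L
  used <- rep(FALSE, length(mps))
  for (i in 1:3) {
    j <- which(!used & ov[, i] >= min_genes)
    if (length(j)) { hit <- hit + 1L; used[j[1]] <- TRUE }
  }
  hit
}
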