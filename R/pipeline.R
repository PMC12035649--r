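#' Build a pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end run (simulate -> QC ->
#' normalise -> NMF programs -> robustness filter -> MP clustering -> cell
#' assignment -> spatial scoring -> MP/TME correlation) with the
#' pipeline's canonical defaults: K = 4..9, 50-gene programs, robustness
#' thresholds 35/10/15 shared genes, founder rule 8 genes / more than 5
#' supporters, accretion at 10 genes, 25-gene conservation, 5% prevalence,
#' 30 score bins (24 for module scores). A single master seed
#' deterministically derives all per-stage seeds.
#'
#' QC thresholds default to the droplet-scale values (300 detected genes,
#' 7500 counts, 100 cells) but are part of the config because synthetic
#' cohorts are far smaller than real droplet data; the bundled analysis
#' scripts scale them to the simulated depth.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort; pass
#'   `NULL` and supply your own samples to [run_pipeline()].
#' @param spatial a [spatial_config()] or `NULL` to skip the spatial
#'   stages.
#' @param min_features,max_counts,min_cells,min_malignant_cells QC
#'   thresholds, see [qc_filter_cells()], [qc_filter_genes()],
#'   [qc_filter_samples()].
#' @param k_range,genes_per_program see [extract_programs()].
#' @param min_intra,min_inter,max_dedup see [select_robust()].
#' @param founder_min_overlap,min_cases,accrete_min_overlap,mp_size see
#'   [cluster_all()].
#' @param min_genes_conserved,min_prevalence,n_bins,n_bins_module,n_ctrl
#'   see [score_cells()], [assign_cells()], [mp_module_scores()].
#' @param seed master seed.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(cohort = cohort_config(), spatial = NULL,
                       min_features = 300, max_counts = 7500,
                       min_cells = 100, min_malignant_cells = 200,
                       k_range = 4:9, genes_per_program = 50,
                       min_intra = 35, min_inter = 10, max_dedup = 15,
                       founder_min_overlap = 8, min_cases = 5,
                       accrete_min_overlap = 10, mp_size = 50,
                       min_genes_conserved = 25, min_prevalence = 0.05,
                       n_bins = 30, n_bins_module = 24, n_ctrl = 100,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(is.null(cohort) || inherits(cohort, "cohort_config"),
            is.null(spatial) || inherits(spatial, "spatial_config"))
  structure(cfg, class = "run_config")
}

stage_seed <- function(master, offset)
  as.integer((as.numeric(master) * 1009 + offset * 9176) %% 2147483647L)

log_line <- function(con, stage, ...) {
  msg <- jsonlite::toJSON(c(list(time = format(Sys.time(), "%H:%M:%S"),
                                 stage = stage), list(...)),
                          auto_unbox = TRUE)
  writeLines(as.character(msg), con)
}

#' Run the full meta-program pipeline
#'
#' Executes every stage in order on a synthetic cohort (or user-supplied
#' samples), writes each stage's artifacts under `out_dir`, and returns a
#' manifest of parameters, artifact md5 hashes and stage summaries.
#' Rerunning with the same config reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` keeps everything in memory and
#'   writes nothing.
#' @param samples optional list of [sample_matrix()] overriding the
#'   synthetic cohort.
#' @return list with `mps`, `assignments`, `programs`, `robust`,
#'   `spatial` (grid + correlations, when configured), `truth`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, samples = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- vapply(1:6, stage_seed, 0L, master = config$seed)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run_log.jsonl"), "w")
    on.exit(close(log_con))
  }
  say <- function(stage, ...) {
    if (!is.null(log_con)) log_line(log_con, stage, ...)
  }

  # 1. data
  truth <- NULL
  if (is.null(samples)) {
    if (is.null(config$cohort)) stop("stage simulate: no cohort config and no samples supplied")
    cc <- config$cohort
    cc$seed <- stage_seed(config$seed, 1L)
    sim <- simulate_cohort(cc)
    samples <- sim$samples
    truth <- sim$truth
    if (!is.null(out_dir)) write_cohort(sim, file.path(out_dir, "cohort"))
  }
  say("simulate", n_samples = length(samples))

  # 2. QC + normalisation
  samples <- tryCatch({
    kept <- qc_filter_samples(samples, config$min_malignant_cells)
    lapply(kept, function(m)
      normalize_for_nmf(qc_filter_genes(
        qc_filter_cells(m, config$min_features, config$max_counts),
        config$min_cells)))
  }, error = function(e) stop("stage qc: ", conditionMessage(e)))
  say("qc", n_samples = length(samples),
      dims = vapply(samples, function(m) paste(dim(m), collapse = "x"), ""))

  # 3. per-sample NMF programs
  programs <- tryCatch(
    unlist(lapply(samples, extract_programs, k_range = config$k_range,
                  genes_per_program = config$genes_per_program,
                  seed = seeds[2]),
           recursive = FALSE),
    error = function(e) stop("stage programs: ", conditionMessage(e)))
  pool <- program_set(programs)
  say("programs", n_programs = length(programs))
  if (!is.null(out_dir))
    write.table(programs_to_table(programs),
                file.path(out_dir, "programs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # 4. robustness filter
  robust <- tryCatch(
    select_robust(pool, config$min_intra, config$min_inter,
                  config$max_dedup),
    error = function(e) stop("stage robust: ", conditionMessage(e)))
  say("robust", n_robust = length(robust))

  # 5. MP clustering
  clusters <- tryCatch(
    cluster_all(robust, config$founder_min_overlap, config$min_cases,
                config$accrete_min_overlap, config$mp_size),
    error = function(e) stop("stage cluster: ", conditionMessage(e)))
  mps <- clusters$mps
  say("cluster", n_mps = length(mps),
      n_unassigned = length(clusters$unassigned))
  if (!is.null(out_dir) && length(mps))
    write_gmt(setNames(lapply(mps, `[[`, "genes"),
                       vapply(mps, `[[`, "", "mp_id")),
              file.path(out_dir, "meta_programs.gmt"))

  # 6. per-cell scoring and assignment
  assignments <- NULL
  if (length(mps)) {
    assignments <- tryCatch(
      lapply(samples, function(m) {
        sc <- score_cells(m, mps, config$min_genes_conserved,
                          n_bins = config$n_bins, n_ctrl = config$n_ctrl,
                          seed = seeds[3])
        assign_cells(sc, config$min_prevalence, sample_id = m$sample_id)
      }),
      error = function(e) stop("stage assign: ", conditionMessage(e)))
    say("assign",
        unresolved = sum(vapply(assignments, function(a)
          sum(a$labels == "unresolved"), 0L)))
    if (!is.null(out_dir)) {
      lab <- do.call(rbind, lapply(assignments, function(a)
        data.frame(cell_id = names(a$labels), sample_id = a$sample_id,
                   mp_label = unname(a$labels))))
      write.table(lab, file.path(out_dir, "cell_labels.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  # 7. spatial stages
  spatial <- NULL
  if (!is.null(config$spatial)) {
    sp_cfg <- config$spatial
    sp_cfg$seed <- stage_seed(config$seed, 4L)
    sp <- simulate_spatial(sp_cfg)
    grid <- sp$grid
    if (length(mps) && !is.null(grid$expression))
      grid <- assign_spot_mp(grid, mps, n_bins = config$n_bins_module,
                             n_ctrl = config$n_ctrl, seed = seeds[5])
    corr <- tryCatch(
      mp_tme_correlation(grid),
      error = function(e) stop("stage spatial: ", conditionMessage(e)))
    spatial <- list(grid = grid, truth = sp$truth, correlation = corr)
    say("spatial", n_spots = nrow(grid$spots),
        n_tumour = sum(grid$is_tumour))
    if (!is.null(out_dir)) {
      write_spot_grid(grid, file.path(out_dir, "spot_grid.tsv"))
      write.table(as.data.frame(corr$pooled),
                  file.path(out_dir, "mp_tme_correlation.tsv"),
                  sep = "\t", quote = FALSE)
    }
  }

  manifest <- list(
    parameters = config[!vapply(config, is.function, TRUE)],
    seed = config$seed,
    n_samples = length(samples),
    n_programs = length(programs),
    n_robust = length(robust),
    n_mps = length(mps))
  if (!is.null(out_dir)) {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    manifest$artifacts <- as.list(tools::md5sum(
      file.path(out_dir, files)))
    names(manifest$artifacts) <- files
    mcfg <- manifest
    mcfg$parameters <- lapply(mcfg$parameters, function(x)
      if (is.object(x)) unclass(x)[!vapply(unclass(x), is.function, TRUE)]
      else x)
    jsonlite::write_json(mcfg, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  list(mps = mps, assignments = assignments, programs = programs,
       robust = robust, unassigned = clusters$unassigned,
       spatial = spatial, truth = truth, samples = samples,
       manifest = manifest)
}
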