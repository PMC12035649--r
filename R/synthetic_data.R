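#' Define a planted co-expression program
#'
#' A planted program is the synthetic ground-truth counterpart of an NMF
#' expression program: a fixed gene set that is jointly up-regulated (by
#' `effect_size`) in the cells where the program is active. Activity is
#' binary per cell so that downstream recovery checks are unambiguous.
#'
#' @param program_id character label.
#' @param genes character vector of member gene ids (default signature size
#'   is 50, matching the meta-program convention).
#' @param activity_rate fraction of cells in which the program is active,
#'   in (0, 1].
#' @param effect_size multiplicative boost of program-gene mean expression
#'   in active cells; must be >= 1 (1 = no effect).
#' @param samples optional character vector restricting the samples that
#'   carry the program; `NULL` means every sample in the cohort.
#' @return An object of class `planted_program`.
#' @export
planted_program <- function(program_id, genes, activity_rate = 0.2,
                            effect_size = 8, samples = NULL) {
  stopifnot(is.character(program_id), length(program_id) == 1L,
            is.character(genes), length(genes) > 0L,
            !anyDuplicated(genes),
            activity_rate > 0, activity_rate <= 1, effect_size >= 1)
  structure(list(program_id = program_id, genes = genes,
                 activity_rate = activity_rate, effect_size = effect_size,
                 samples = samples),
            class = "planted_program")
}

#' Configuration of a synthetic multi-sample cohort
#'
#' Counts are negative-binomial: gene g in cell j has mean
#' `baseline_mean` times the product of the `effect_size`s of all programs
#' active in j that contain g, with variance `mu + dispersion * mu^2`.
#' The seed fully determines the output.
#'
#' @param n_samples number of samples.
#' @param n_genes genes per sample; must cover the union of planted gene
#'   sets.
#' @param cells_per_sample cells per sample.
#' @param shared_programs list of [planted_program()]s present in two or
#'   more samples (all samples unless a program restricts itself); their
#'   gene sets must be pairwise disjoint.
#' @param private_programs optional list (one entry per sample, may be
#'   `NULL`) of sample-specific [planted_program()] lists.
#' @param baseline_mean per-gene per-cell mean count in the absence of any
#'   program (default 0.5, a typical droplet-depth order of magnitude).
#' @param dispersion negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2` (default 0.5).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 8, n_genes = 300,
                          cells_per_sample = 300,
                          shared_programs = list(),
                          private_programs = NULL,
                          baseline_mean = 0.5, dispersion = 0.5,
                          seed = 1) {
  stopifnot(n_samples >= 1, n_genes >= 1, cells_per_sample >= 1,
            baseline_mean > 0, dispersion > 0)
  shared_genes <- lapply(shared_programs, `[[`, "genes")
  if (length(shared_genes) > 1L) {
    pooled <- unlist(shared_genes)
    if (anyDuplicated(pooled))
      stop("gene sets of shared planted programs must be pairwise disjoint")
  }
  if (!is.null(private_programs))
    stopifnot(length(private_programs) == n_samples)
  all_genes <- unique(c(unlist(shared_genes),
                        unlist(lapply(unlist(private_programs,
                                             recursive = FALSE),
                                      function(p) p$genes))))
  if (length(all_genes) > n_genes)
    stop(sprintf("n_genes (%d) smaller than union of planted gene sets (%d)",
                 n_genes, length(all_genes)))
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 cells_per_sample = cells_per_sample,
                 shared_programs = shared_programs,
                 private_programs = private_programs,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 seed = seed),
            class = "cohort_config")
}

# Default gene universe: planted genes first, fillers after, zero-padded ids.
cohort_gene_ids <- function(config) {
  planted <- unique(c(
    unlist(lapply(config$shared_programs, `[[`, "genes")),
    unlist(lapply(unlist(config$private_programs, recursive = FALSE),
                  function(p) p$genes))))
  fillers <- sprintf("g%04d", seq_len(config$n_genes))
  fillers <- setdiff(fillers, planted)
  c(planted, fillers)[seq_len(config$n_genes)]
}

#' Simulate a multi-sample single-cell cohort with planted programs
#'
#' @param config a [cohort_config()].
#' @return A list with elements
#'   * `samples`: list of [sample_matrix()] (all cells flagged malignant),
#'   * `truth`: data frame with one row per cell (`sample_id`, `cell_id`,
#'     `active_programs` as a comma-joined label, empty when none),
#'   * `programs`: data frame describing every planted program and the
#'     samples carrying it.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gene_ids <- cohort_gene_ids(config)
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  size_nb <- 1 / config$dispersion

  with_seed(config$seed, {
    truth <- vector("list", config$n_samples)
    samples <- vector("list", config$n_samples)
    prog_rows <- list()
    for (s in seq_len(config$n_samples)) {
      sid <- sample_ids[s]
      progs <- Filter(function(p) is.null(p$samples) || sid %in% p$samples,
                      config$shared_programs)
      if (!is.null(config$private_programs) &&
          !is.null(config$private_programs[[s]]))
        progs <- c(progs, config$private_programs[[s]])
      n_cells <- config$cells_per_sample
      cell_ids <- sprintf("%s_c%04d", sid, seq_len(n_cells))

      mu <- matrix(config$baseline_mean, config$n_genes, n_cells,
                   dimnames = list(gene_ids, cell_ids))
      active <- matrix("", 0, 0)
      active_lab <- rep("", n_cells)
      for (p in progs) {
        on <- runif(n_cells) < p$activity_rate
        mu[p$genes, on] <- mu[p$genes, on] * p$effect_size
        active_lab[on] <- ifelse(active_lab[on] == "", p$program_id,
                                 paste(active_lab[on], p$program_id,
                                       sep = ","))
        prog_rows[[length(prog_rows) + 1L]] <-
          data.frame(program_id = p$program_id, sample_id = sid,
                     n_genes = length(p$genes),
                     activity_rate = p$activity_rate,
                     effect_size = p$effect_size, n_active = sum(on))
      }
      counts <- matrix(rnbinom(length(mu), mu = mu, size = size_nb),
                       nrow = config$n_genes, dimnames = dimnames(mu))
      samples[[s]] <- sample_matrix(counts, sid,
                                    malignant = rep(TRUE, n_cells))
      truth[[s]] <- data.frame(sample_id = sid, cell_id = cell_ids,
                               active_programs = active_lab)
    }
    list(samples = samples,
         truth = do.call(rbind, truth),
         programs = if (length(prog_rows)) do.call(rbind, prog_rows)
                    else data.frame())
  })
}

#' Configuration of a synthetic spatial slide
#'
#' Spots sit on a square `n_rows` x `n_cols` lattice. Each meta-program
#' named in `association` gets a spatially smooth activity field in
#' \[0, 1\] (iterated 8-neighbour smoothing of uniform noise); per-spot
#' cell-type weights are a Dirichlet draw whose concentration for an
#' associated cell type is `base_concentration + slope * activity`, so a
#' positive slope plants a spatial MP/cell-type association that the
#' tumour-neighbourhood correlation should recover.
#'
#' @param n_rows,n_cols grid dimensions (each >= 3).
#' @param cell_types character vector of cell-type labels.
#' @param association list of `list(mp_id=, cell_type=, slope=)` triples;
#'   `slope = 0` entries define null pairs.
#' @param tumour_region predicate `function(row, col)` returning whether a
#'   spot is a tumour spot; `NULL` flags every spot.
#' @param base_concentration Dirichlet concentration of every cell type
#'   before association shifts (default 1).
#' @param n_smooth smoothing passes for the activity fields (default 3).
#' @param mp_genes optional named list (mp_id -> gene vector); when given,
#'   per-spot expression is simulated with those genes boosted by the MP
#'   activity so spots can be scored and assigned like cells.
#' @param n_genes,baseline_mean,dispersion,effect_size expression-layer
#'   parameters, used only when `mp_genes` is supplied.
#' @param seed integer RNG seed.
#' @return An object of class `spatial_config`.
#' @export
spatial_config <- function(n_rows = 40, n_cols = 40,
                           cell_types = c("fibroblast", "T_cell", "B_cell",
                                          "myeloid", "endothelial"),
                           association = list(),
                           tumour_region = NULL,
                           base_concentration = 1, n_smooth = 3,
                           mp_genes = NULL, n_genes = 300,
                           baseline_mean = 5, dispersion = 0.5,
                           effect_size = 8, seed = 1) {
  if (n_rows < 3 || n_cols < 3)
    stop("grid must be at least 3 x 3 (no interior spot otherwise)")
  for (a in association)
    stopifnot(!is.null(a$mp_id), a$cell_type %in% cell_types,
              is.numeric(a$slope))
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_types = cell_types,
                 association = association, tumour_region = tumour_region,
                 base_concentration = base_concentration,
                 n_smooth = n_smooth, mp_genes = mp_genes,
                 n_genes = n_genes, baseline_mean = baseline_mean,
                 dispersion = dispersion, effect_size = effect_size,
                 seed = seed),
            class = "spatial_config")
}

# Smooth a matrix by repeated truncated 3x3 (Moore) box averaging.
smooth_field <- function(x, passes) {
  nr <- nrow(x); nc <- ncol(x)
  for (i in seq_len(passes)) {
    acc <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      rt <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      ct <- max(1, 1 - dc):min(nc, nc - dc)
      acc[rt, ct] <- acc[rt, ct] + x[rs, cs]
      n[rt, ct] <- n[rt, ct] + 1
    }
    x <- acc / n
  }
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' Simulate a spatial slide with planted MP/cell-type association
#'
#' @param config a [spatial_config()].
#' @return A list with the generated [spot_grid()] (`grid`) and the ground
#'   truth (`truth`): per-spot MP activities and the association table.
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "spatial_config"))
  nr <- config$n_rows; nc <- config$n_cols
  coords <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  coords <- coords[order(coords$row, coords$col), ]
  spot_ids <- sprintf("spot_%03d_%03d", coords$row, coords$col)
  mp_ids <- unique(vapply(config$association, `[[`, "", "mp_id"))
  if (length(mp_ids) == 0L) mp_ids <- "MP1"

  with_seed(config$seed, {
    activity <- sapply(mp_ids, function(id) NULL, simplify = FALSE)
    for (id in mp_ids) {
      f <- smooth_field(matrix(runif(nr * nc), nr, nc), config$n_smooth)
      activity[[id]] <- f[cbind(coords$row, coords$col)]
    }
    act_mat <- do.call(cbind, activity)
    colnames(act_mat) <- mp_ids
    rownames(act_mat) <- spot_ids

    alpha <- matrix(config$base_concentration, nrow(coords),
                    length(config$cell_types),
                    dimnames = list(spot_ids, config$cell_types))
    for (a in config$association)
      alpha[, a$cell_type] <- alpha[, a$cell_type] +
        a$slope * act_mat[, a$mp_id]
    g <- matrix(rgamma(length(alpha), shape = alpha), nrow = nrow(alpha),
                dimnames = dimnames(alpha))
    weights <- g / rowSums(g)

    is_tum <- if (is.null(config$tumour_region)) rep(TRUE, nrow(coords))
              else mapply(config$tumour_region, coords$row, coords$col)

    expr <- NULL
    if (!is.null(config$mp_genes)) {
      planted <- unlist(config$mp_genes)
      gene_ids <- unique(c(planted, sprintf("g%04d",
                                            seq_len(config$n_genes))))
      gene_ids <- gene_ids[seq_len(max(config$n_genes, length(planted)))]
      mu <- matrix(config$baseline_mean, length(gene_ids), nrow(coords),
                   dimnames = list(gene_ids, spot_ids))
      for (id in names(config$mp_genes)) {
        act <- if (id %in% colnames(act_mat)) act_mat[, id]
               else rep(0, nrow(coords))
        boost <- 1 + (config$effect_size - 1) * act
        mu[config$mp_genes[[id]], ] <-
          mu[config$mp_genes[[id]], , drop = FALSE] *
          rep(boost, each = length(config$mp_genes[[id]]))
      }
      expr <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    }

    grid <- spot_grid(spots = data.frame(spot_id = spot_ids,
                                         row = coords$row,
                                         col = coords$col),
                      is_tumour = is_tum, weights = weights,
                      spot_scores = act_mat, expression = expr)
    assoc <- if (length(config$association))
      do.call(rbind, lapply(config$association, as.data.frame))
      else data.frame()
    list(grid = grid,
         truth = list(activity = act_mat, association = assoc))
  })
}
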