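#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>...`.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character gene vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "consensusMP") {
  stopifnot(!is.null(names(sets)))
  lines <- mapply(function(nm, genes, d)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
}

#' Flatten NMF programs to a long table
#'
#' @param programs list of [nmf_program()].
#' @return data frame with columns sample_id, rank_k, factor_index, gene,
#'   weight, gene_rank.
#' @export
programs_to_table <- function(programs) {
  do.call(rbind, lapply(programs, function(p)
    data.frame(sample_id = p$sample_id, rank_k = p$rank_k,
               factor_index = p$factor_index, gene = p$genes,
               weight = unname(p$weights),
               gene_rank = seq_along(p$genes))))
}

#' Rebuild NMF programs from a long table
#'
#' @param tab a data frame in the [programs_to_table()] layout.
#' @return list of [nmf_program()].
#' @export
table_to_programs <- function(tab) {
  key <- interaction(tab$sample_id, tab$rank_k, tab$factor_index,
                     drop = TRUE)
  lapply(split(tab, key), function(d) {
    d <- d[order(d$gene_rank), ]
    nmf_program(d$sample_id[1], d$rank_k[1], d$factor_index[1],
                d$gene, d$weight)
  })
}

#' Write a synthetic cohort to disk
#'
#' One subdirectory per sample with Matrix Market counts plus gene and
#' barcode sidecars, the ground-truth table, and the planted-program table.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$samples) {
    sdir <- file.path(dir, m$sample_id)
    dir.create(sdir, showWarnings = FALSE)
    Matrix::writeMM(m$counts, file.path(sdir, "matrix.mtx"))
    writeLines(rownames(m$counts), file.path(sdir, "genes.tsv"))
    writeLines(colnames(m$counts), file.path(sdir, "barcodes.tsv"))
  }
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$programs, file.path(dir, "planted_programs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read one sample from a Matrix Market directory
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @param sample_id sample label; defaults to the directory name.
#' @return a [sample_matrix()] (all cells flagged malignant, matching the
#'   synthetic writer).
#' @export
read_sample_mtx <- function(dir, sample_id = basename(dir)) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")),
               "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  sample_matrix(counts, sample_id,
                malignant = rep(TRUE, ncol(counts)))
}

#' Write a spot grid as TSV
#'
#' Columns: spot_id, row, col, is_tumour, one column per cell-type weight,
#' then any spot-score columns prefixed `score_`.
#'
#' @param grid a [spot_grid()].
#' @param path output file.
#' @export
write_spot_grid <- function(grid, path) {
  d <- cbind(grid$spots,
             is_tumour = unname(grid$is_tumour),
             as.data.frame(grid$weights))
  if (!is.null(grid$spot_scores)) {
    sc <- as.data.frame(grid$spot_scores)
    names(sc) <- paste0("score_", names(sc))
    d <- cbind(d, sc)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spot grid written by [write_spot_grid()]
#'
#' @param path TSV file.
#' @param cell_types weight column names; defaults to every column that is
#'   not spot metadata or a `score_` column.
#' @return a [spot_grid()].
#' @export
read_spot_grid <- function(path, cell_types = NULL) {
  d <- read.delim(path, check.names = FALSE)
  meta <- c("spot_id", "row", "col", "is_tumour")
  score_cols <- grep("^score_", names(d), value = TRUE)
  if (is.null(cell_types))
    cell_types <- setdiff(names(d), c(meta, score_cols))
  scores <- NULL
  if (length(score_cols)) {
    scores <- as.matrix(d[score_cols])
    colnames(scores) <- sub("^score_", "", score_cols)
  }
  spot_grid(d[c("spot_id", "row", "col")],
            is_tumour = as.logical(d$is_tumour),
            weights = as.matrix(d[cell_types]),
            spot_scores = scores)
}
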