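#' Construct a per-sample expression matrix
#'
#' The basic container for one tumour sample: a genes x cells matrix of raw
#' counts, an optional variance-stabilised `normalized` layer (filled by
#' [normalize_for_nmf()]), and an optional per-cell malignant flag used by
#' the sample-level QC filter.
#'
#' @param counts genes x cells matrix (base or `Matrix` sparse) of
#'   non-negative integer counts with unique row (gene) and column (cell)
#'   names.
#' @param sample_id character scalar identifying the sample.
#' @param malignant optional logical vector, one entry per cell, flagging
#'   malignant cells (ground truth in synthetic data, upstream annotation in
#'   real data).
#' @param normalized optional genes x cells numeric matrix, the
#'   variance-stabilised layer consumed by NMF. Usually left `NULL` and
#'   filled by [normalize_for_nmf()].
#'
#' @return An object of class `sample_matrix`.
#' @export
sample_matrix <- function(counts, sample_id, malignant = NULL,
                          normalized = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE),
                  "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.null(malignant)) {
    stopifnot(is.logical(malignant), length(malignant) == ncol(counts))
    names(malignant) <- colnames(counts)
  }
  if (!is.null(normalized)) {
    stopifnot(identical(dim(normalized), dim(counts)))
    if (min(normalized) < 0) stop("normalized layer must be non-negative")
  }
  structure(list(sample_id = sample_id, counts = counts,
                 normalized = normalized, malignant = malignant),
            class = "sample_matrix")
}

#' @export
dim.sample_matrix <- function(x) dim(x$counts)

#' @method print sample_matrix
#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> %s: %d genes x %d cells%s%s\n",
              x$sample_id, nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "" else " (normalized)",
              if (is.null(x$malignant)) ""
              else sprintf(", %d malignant", sum(x$malignant))))
  invisible(x)
}

genes <- function(m) rownames(m$counts)
cells <- function(m) colnames(m$counts)

# Subset a sample_matrix keeping all layers aligned.
subset_sample <- function(m, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(m$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(m$counts)) else cells
  m$counts <- m$counts[gi, ci, drop = FALSE]
  if (!is.null(m$normalized))
    m$normalized <- m$normalized[gi, ci, drop = FALSE]
  if (!is.null(m$malignant)) m$malignant <- m$malignant[ci]
  m
}

#' Filter cells on detected genes and library size
#'
#' Retains cells with more than `min_features` detected genes (count > 0)
#' and fewer than `max_counts` total counts. Both inequalities are strict;
#' the defaults are the droplet-QC thresholds commonly used to drop cells
#' with poor coverage or excessive ambient RNA.
#'
#' @param m a [sample_matrix()].
#' @param min_features keep cells with number of detected genes strictly
#'   greater than this (default 300).
#' @param max_counts keep cells with total counts strictly below this
#'   (default 7500).
#' @return The filtered `sample_matrix`, cell order preserved.
#' @export
qc_filter_cells <- function(m, min_features = 300, max_counts = 7500) {
  stopifnot(inherits(m, "sample_matrix"))
  n_feat <- Matrix::colSums(m$counts > 0)
  n_count <- Matrix::colSums(m$counts)
  keep <- which(n_feat > min_features & n_count < max_counts)
  if (length(keep) == 0L)
    stop(sprintf("sample '%s': no cells pass QC (min_features=%d, max_counts=%d)",
                 m$sample_id, min_features, max_counts))
  subset_sample(m, cells = keep)
}

#' Filter genes on detection breadth
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells.
#'
#' @param m a [sample_matrix()].
#' @param min_cells minimum number of cells a gene must be detected in
#'   (default 100).
#' @return The filtered `sample_matrix`, gene order preserved.
#' @export
qc_filter_genes <- function(m, min_cells = 100) {
  stopifnot(inherits(m, "sample_matrix"))
  keep <- which(Matrix::rowSums(m$counts > 0) >= min_cells)
  if (length(keep) == 0L)
    warning(sprintf("sample '%s': no genes detected in >= %d cells",
                    m$sample_id, min_cells))
  subset_sample(m, genes = keep)
}

#' Drop samples with too few malignant cells
#'
#' @param cohort list of [sample_matrix()] objects, each carrying a
#'   `malignant` flag vector.
#' @param min_malignant_cells samples with fewer flagged cells than this are
#'   dropped (default 200).
#' @return The retained sub-list, input order preserved.
#' @export
qc_filter_samples <- function(cohort, min_malignant_cells = 200) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  n_mal <- vapply(cohort, function(m) {
    if (is.null(m$malignant))
      stop(sprintf("sample '%s' has no malignant flag", m$sample_id))
    sum(m$malignant)
  }, numeric(1))
  kept <- cohort[n_mal >= min_malignant_cells]
  if (length(kept) == 0L)
    stop(sprintf("no sample has >= %d malignant cells", min_malignant_cells))
  kept
}

# Per-cell log-normalised expression: log2(1 + CPM/10), dense genes x cells.
log_normalize <- function(counts) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  cpm <- as.matrix(counts) %*% diag(1e6 / tot, length(tot))
  dimnames(cpm) <- dimnames(counts)
  log2(1 + cpm / 10)
}

#' Variance-stabilising normalisation for NMF
#'
#' Fills the `normalized` layer with `log2(1 + CPM/10)` per cell, centred
#' per gene across cells, negatives clipped to zero. Clipping keeps the
#' layer non-negative as NMF requires; after centring, a positive entry
#' marks above-average expression of that gene in that cell.
#'
#' @param m a [sample_matrix()] with a counts layer.
#' @return `m` with the `normalized` layer filled.
#' @export
normalize_for_nmf <- function(m) {
  stopifnot(inherits(m, "sample_matrix"))
  le <- log_normalize(m$counts)
  centred <- le - rowMeans(le)
  m$normalized <- pmax(centred, 0)
  m
}
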