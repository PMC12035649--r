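# Centered log-normalized expression and average-expression bins shared by
# the scoring functions. Bins are equal-occupancy over genes ranked by
# average log-expression across cells.
centered_expression <- function(counts) {
  le <- log_normalize(counts)
  le - rowMeans(le)
}

expression_bins <- function(counts, n_bins) {
  avg <- rowMeans(log_normalize(counts))
  r <- rank(avg, ties.method = "first")
  bins <- floor((r - 1) * n_bins / length(r)) + 1L
  setNames(bins, rownames(counts))
}

#' Bin-matched control signature score
#'
#' Tirosh-style module score: for each cell, the mean centred
#' log-normalised expression of the signature genes minus the mean over a
#' control gene set drawn, per signature gene, from that gene's
#' average-expression bin. Subtracting expression-matched controls removes
#' the component of the signature mean explained by library depth and
#' overall expression level. Signature genes absent from the matrix are
#' ignored; control draws are without replacement within a bin (the whole
#' bin when it holds fewer than `n_ctrl` genes) and pooled over signature
#' genes without duplication.
#'
#' @param m a [sample_matrix()], or a genes x cells count matrix.
#' @param genes character vector, the signature.
#' @param n_bins number of average-expression bins (default 30).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed RNG seed for the control draws; fixed seed gives
#'   bit-identical scores.
#' @return named numeric vector, one score per cell.
#' @export
signature_score <- function(m, genes, n_bins = 30, n_ctrl = 100,
                            seed = 1L) {
  counts <- if (inherits(m, "sample_matrix")) m$counts else m
  sig <- intersect(genes, rownames(counts))
  if (length(sig) == 0L)
    stop("no signature gene present in the matrix")
  centred <- centered_expression(counts)
  bins <- expression_bins(counts, n_bins)
  ctrl <- with_seed(seed, {
    drawn <- lapply(sig, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    })
    unique(unlist(drawn))
  })
  colMeans(centred[sig, , drop = FALSE]) -
    colMeans(centred[ctrl, , drop = FALSE])
}

#' Score cells against meta-programs with a conservation gate
#'
#' Scores each MP via [signature_score()], but only MPs with at least
#' `min_genes_conserved` of their genes present in the matrix; the rest are
#' excluded for this sample (reported in the `excluded_mps` attribute).
#'
#' @param m a [sample_matrix()].
#' @param mps list of [meta_program()].
#' @param min_genes_conserved minimum MP genes present (default 25, i.e.
#'   half of a 50-gene signature).
#' @param n_bins,n_ctrl,seed forwarded to [signature_score()].
#' @return cells x MP numeric matrix (one column per scored MP).
#' @export
score_cells <- function(m, mps, min_genes_conserved = 25, n_bins = 30,
                        n_ctrl = 100, seed = 1L) {
  stopifnot(length(mps) > 0L)
  counts <- if (inherits(m, "sample_matrix")) m$counts else m
  present <- vapply(mps, function(mp)
    length(intersect(mp$genes, rownames(counts))), 0L)
  ok <- present >= min_genes_conserved
  if (!any(ok))
    stop(sprintf("no MP has >= %d genes conserved in the matrix",
                 min_genes_conserved))
  cols <- lapply(mps[ok], function(mp)
    signature_score(m, mp$genes, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed))
  scores <- do.call(cbind, cols)
  colnames(scores) <- vapply(mps[ok], `[[`, "", "mp_id")
  attr(scores, "excluded_mps") <- vapply(mps[!ok], `[[`, "", "mp_id")
  scores
}

#' Assign cells to meta-programs with a prevalence rule
#'
#' Each cell provisionally takes the arg-max MP of its score row (ties go
#' to the first MP column). An MP must label at least `min_prevalence` of
#' the cells to be retained; cells of a dropped MP are labelled
#' `"unresolved"` rather than reassigned. The drop is a single pass, and
#' post-drop prevalence is logged so residual sub-threshold MPs are
#' visible.
#'
#' @param scores cells x MP numeric matrix (from [score_cells()]).
#' @param min_prevalence retention threshold as a fraction of cells
#'   (default 0.05).
#' @param sample_id optional label stored on the result.
#' @return Object of class `cell_assignment`: `labels` (named character,
#'   MP id or `"unresolved"`), `retained_mps`, `prevalence` (post-drop
#'   label fractions), and the score matrix.
#' @export
assign_cells <- function(scores, min_prevalence = 0.05,
                         sample_id = NA_character_) {
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  mp_ids <- colnames(scores)
  top <- mp_ids[apply(scores, 1, which.max)]
  n <- nrow(scores)
  prev <- vapply(mp_ids, function(id) sum(top == id) / n, 0)
  retained <- mp_ids[prev >= min_prevalence]
  labels <- ifelse(top %in% retained, top, "unresolved")
  names(labels) <- rownames(scores)
  structure(list(sample_id = sample_id, scores = scores, labels = labels,
                 retained_mps = retained,
                 prevalence = prev[retained]),
            class = "cell_assignment")
}

#' @method print cell_assignment
#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf("<cell_assignment> %s: %d cells, %d retained MPs, %d unresolved\n",
              x$sample_id, length(x$labels), length(x$retained_mps),
              sum(x$labels == "unresolved")))
  invisible(x)
}

#' Per-cell MP module scores
#'
#' The continuous counterpart of assignment scoring: every MP is scored by
#' [signature_score()] with the module-score binning default (24 bins) and
#' no conservation gate, yielding the cell x MP matrix used for MP/MP and
#' MP/TME correlation analyses.
#'
#' @param m a [sample_matrix()].
#' @param mps list of [meta_program()].
#' @param n_bins,n_ctrl,seed forwarded to [signature_score()].
#' @return cells x MP numeric matrix.
#' @export
mp_module_scores <- function(m, mps, n_bins = 24, n_ctrl = 100,
                             seed = 1L) {
  stopifnot(length(mps) > 0L)
  cols <- lapply(mps, function(mp)
    signature_score(m, mp$genes, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed))
  scores <- do.call(cbind, cols)
  colnames(scores) <- vapply(mps, `[[`, "", "mp_id")
  scores
}

#' Pearson correlation between MP score columns
#'
#' @param scores cells x MP numeric matrix with at least 3 rows.
#' @return symmetric MP x MP Pearson matrix with unit diagonal;
#'   zero-variance columns give `NA` entries with a warning, never a
#'   silent 0.
#' @export
mp_correlation_matrix <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) >= 3L)
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance score column(s): ",
            paste(colnames(scores)[sds == 0], collapse = ", "),
            " (correlations set to NA)")
  r <- suppressWarnings(cor(scores))
  diag(r) <- 1
  r
}
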