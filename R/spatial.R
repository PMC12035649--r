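#' A spatial slide of spots on a lattice
#'
#' Holds spot coordinates, tumour flags, per-spot cell-type deconvolution
#' weights, optional per-spot signature scores and expression, and optional
#' per-spot MP labels.
#'
#' @param spots data frame with columns `spot_id`, `row`, `col`;
#'   (row, col) pairs must be unique.
#' @param is_tumour logical vector, one entry per spot.
#' @param weights spots x cell-type numeric matrix; entries >= 0, each row
#'   summing to at most 1 (a deconvolution may leave mass unexplained).
#' @param spot_scores optional spots x signature numeric matrix.
#' @param expression optional genes x spots count matrix.
#' @param mp_label optional named character vector of MP labels for tumour
#'   spots.
#' @return Object of class `spot_grid`.
#' @export
spot_grid <- function(spots, is_tumour, weights, spot_scores = NULL,
                      expression = NULL, mp_label = NULL) {
  stopifnot(is.data.frame(spots),
            all(c("spot_id", "row", "col") %in% names(spots)),
            !anyDuplicated(spots$spot_id),
            is.logical(is_tumour), length(is_tumour) == nrow(spots))
  if (anyDuplicated(spots[c("row", "col")]))
    stop("duplicate (row, col) coordinates")
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == nrow(spots))
  if (min(weights) < 0) stop("weights must be non-negative")
  if (any(rowSums(weights) > 1 + 1e-9))
    stop("per-spot weights must sum to at most 1")
  rownames(weights) <- spots$spot_id
  if (!is.null(spot_scores)) {
    spot_scores <- as.matrix(spot_scores)
    stopifnot(nrow(spot_scores) == nrow(spots))
    rownames(spot_scores) <- spots$spot_id
  }
  names(is_tumour) <- spots$spot_id
  structure(list(spots = spots, is_tumour = is_tumour, weights = weights,
                 spot_scores = spot_scores, expression = expression,
                 mp_label = mp_label),
            class = "spot_grid")
}

#' @method print spot_grid
#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("<spot_grid> %d spots (%d tumour), %d cell types%s\n",
              nrow(x$spots), sum(x$is_tumour), ncol(x$weights),
              if (is.null(x$spot_scores)) ""
              else sprintf(", %d score columns", ncol(x$spot_scores))))
  invisible(x)
}

#' Spots adjacent to a spot
#'
#' Default geometry is the 8-spot Moore neighbourhood on the square
#' lattice: the existing grid spots among positions (row +/- 1,
#' col +/- 1), the spot itself excluded. Interior spots have 8 neighbours,
#' edges 5, corners 3. `mode = "hex"` instead uses the 6-neighbour
#' hexagonal adjacency of Visium-style array coordinates (same row at
#' col +/- 2, adjacent rows at col +/- 1).
#'
#' @param grid a [spot_grid()].
#' @param spot_id a spot id in the grid.
#' @param mode `"moore"` (default) or `"hex"`.
#' @return character vector of neighbouring spot ids (possibly empty).
#' @export
neighbourhood <- function(grid, spot_id, mode = c("moore", "hex")) {
  mode <- match.arg(mode)
  i <- match(spot_id, grid$spots$spot_id)
  if (is.na(i)) stop(sprintf("spot '%s' not in grid", spot_id))
  r <- grid$spots$row[i]; cc <- grid$spots$col[i]
  offs <- if (mode == "moore")
    cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))[-5, ]
  else
    cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-2, 2, -1, 1, -1, 1))
  key <- paste(grid$spots$row, grid$spots$col)
  hit <- match(paste(r + offs[, 1], cc + offs[, 2]), key)
  grid$spots$spot_id[hit[!is.na(hit)]]
}

# resolve a named column from weights first, then spot_scores
grid_column <- function(grid, column) {
  if (column %in% colnames(grid$weights)) return(grid$weights[, column])
  if (!is.null(grid$spot_scores) &&
      column %in% colnames(grid$spot_scores))
    return(grid$spot_scores[, column])
  stop(sprintf("column '%s' found in neither weights nor spot_scores",
               column))
}

#' Tumour neighbourhood score of one spot
#'
#' Sums a column's value (a cell type's deconvolution weight, or a per-spot
#' signature score) over the spots adjacent to a tumour spot. Truncated at
#' grid edges: available neighbours are summed with no renormalisation.
#'
#' @param grid a [spot_grid()].
#' @param spot_id a tumour spot id.
#' @param column a cell-type (weights) or signature (spot_scores) column
#'   name.
#' @param mode neighbourhood geometry, see [neighbourhood()].
#' @return numeric scalar.
#' @export
neighbourhood_score <- function(grid, spot_id, column,
                                mode = c("moore", "hex")) {
  if (!isTRUE(grid$is_tumour[[spot_id]]))
    stop(sprintf("'%s' is not a tumour spot", spot_id))
  nb <- neighbourhood(grid, spot_id, mode = match.arg(mode))
  sum(grid_column(grid, column)[nb])
}

#' Neighbourhood scores of all tumour spots
#'
#' @param grid a [spot_grid()].
#' @param columns column names to score; defaults to every cell-type
#'   weight column.
#' @param mode neighbourhood geometry, see [neighbourhood()].
#' @return numeric matrix, tumour spots x columns.
#' @export
neighbourhood_score_table <- function(grid, columns = NULL,
                                      mode = c("moore", "hex")) {
  mode <- match.arg(mode)
  if (is.null(columns)) columns <- colnames(grid$weights)
  tum <- grid$spots$spot_id[grid$is_tumour]
  vals <- vapply(columns, grid_column, numeric(nrow(grid$spots)),
                 grid = grid)
  if (!is.matrix(vals))
    vals <- matrix(vals, ncol = length(columns),
                   dimnames = list(grid$spots$spot_id, columns))
  rownames(vals) <- grid$spots$spot_id
  res <- vapply(tum, function(s) {
    nb <- neighbourhood(grid, s, mode = mode)
    colSums(vals[nb, , drop = FALSE])
  }, numeric(length(columns)))
  out <- if (is.matrix(res)) t(res)
         else matrix(res, ncol = length(columns))
  dimnames(out) <- list(tum, columns)
  out
}

#' Score and label tumour spots with meta-programs
#'
#' Scores every spot against each MP with [signature_score()] on the
#' spot expression matrix and assigns each tumour spot the arg-max MP
#' (ties: first MP in input order). Non-tumour spots are never labelled.
#' MPs with no genes in the matrix are skipped with a warning; if none can
#' be scored every tumour spot is labelled `"unresolved"`.
#'
#' @param grid a [spot_grid()].
#' @param mps list of [meta_program()].
#' @param spot_expression genes x spots count matrix; defaults to the
#'   grid's own expression layer.
#' @param n_bins,n_ctrl,seed forwarded to [signature_score()]
#'   (module-score binning, 24 bins, by default).
#' @return the grid with `spot_scores` (MP columns) and `mp_label` filled.
#' @export
assign_spot_mp <- function(grid, mps, spot_expression = grid$expression,
                           n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(grid, "spot_grid"), length(mps) > 0L)
  if (is.null(spot_expression))
    stop("no spot expression available")
  scorable <- vapply(mps, function(mp)
    length(intersect(mp$genes, rownames(spot_expression))) > 0L, TRUE)
  if (!all(scorable))
    warning("MP(s) with no genes in the spot matrix skipped: ",
            paste(vapply(mps[!scorable], `[[`, "", "mp_id"),
                  collapse = ", "))
  tum <- grid$spots$spot_id[grid$is_tumour]
  if (!any(scorable)) {
    grid$mp_label <- setNames(rep("unresolved", length(tum)), tum)
    return(grid)
  }
  scores <- do.call(cbind, lapply(mps[scorable], function(mp)
    signature_score(spot_expression, mp$genes, n_bins = n_bins,
                    n_ctrl = n_ctrl, seed = seed)))
  colnames(scores) <- vapply(mps[scorable], `[[`, "", "mp_id")
  scores <- scores[grid$spots$spot_id, , drop = FALSE]
  if (is.null(grid$spot_scores)) grid$spot_scores <- scores
  else {
    keep <- setdiff(colnames(grid$spot_scores), colnames(scores))
    grid$spot_scores <- cbind(grid$spot_scores[, keep, drop = FALSE],
                              scores)
  }
  grid$mp_label <- setNames(
    colnames(scores)[apply(scores[tum, , drop = FALSE], 1, which.max)],
    tum)
  grid
}

#' Correlate MP scores with neighbourhood cell-type scores
#'
#' For every (MP score column, target column) pair, the Pearson
#' correlation between the MP score at tumour spots and the target's
#' neighbourhood score at the same spots, pooled over all supplied slides;
#' per-slide matrices are returned alongside. Pooling is over raw spot
#' rows with no per-slide standardisation, so a single slide reproduces
#' its own per-slide matrix exactly.
#'
#' @param grids list of [spot_grid()]s (slides), each with MP score
#'   columns in `spot_scores`.
#' @param mp_cols MP score columns; default every `spot_scores` column of
#'   the first slide.
#' @param target_cols neighbourhood target columns; default every weight
#'   column of the first slide.
#' @param mode neighbourhood geometry, see [neighbourhood()].
#' @return list with `pooled` (MP x target Pearson matrix), `per_slide`
#'   (list of matrices), `n_spots` (pooled tumour spot count). Zero
#'   variance in a pooled series yields `NA` with a warning.
#' @export
mp_tme_correlation <- function(grids, mp_cols = NULL, target_cols = NULL,
                               mode = c("moore", "hex")) {
  mode <- match.arg(mode)
  if (inherits(grids, "spot_grid")) grids <- list(grids)
  stopifnot(length(grids) > 0L)
  if (is.null(mp_cols)) mp_cols <- colnames(grids[[1]]$spot_scores)
  if (is.null(target_cols)) target_cols <- colnames(grids[[1]]$weights)
  stopifnot(length(mp_cols) > 0L, length(target_cols) > 0L)

  per_slide_data <- lapply(grids, function(g) {
    tum <- g$spots$spot_id[g$is_tumour]
    list(mp = g$spot_scores[tum, mp_cols, drop = FALSE],
         nb = neighbourhood_score_table(g, target_cols, mode = mode))
  })
  corr_of <- function(mp, nb) {
    sd_mp <- apply(mp, 2, stats::sd); sd_nb <- apply(nb, 2, stats::sd)
    if (any(c(sd_mp, sd_nb) == 0))
      warning("zero-variance series: ",
              paste(c(colnames(mp)[sd_mp == 0],
                      colnames(nb)[sd_nb == 0]), collapse = ", "))
    suppressWarnings(cor(mp, nb))
  }
  pooled_mp <- do.call(rbind, lapply(per_slide_data, `[[`, "mp"))
  pooled_nb <- do.call(rbind, lapply(per_slide_data, `[[`, "nb"))
  if (nrow(pooled_mp) < 3L) stop("need at least 3 pooled tumour spots")
  list(pooled = corr_of(pooled_mp, pooled_nb),
       per_slide = lapply(per_slide_data, function(d)
         corr_of(d$mp, d$nb)),
       n_spots = nrow(pooled_mp))
}
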