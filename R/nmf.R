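#' One NMF expression program
#'
#' A program is one factor of one per-sample factorisation, represented by
#' its top genes ranked by NMF basis coefficient.
#'
#' @param sample_id sample of origin.
#' @param rank_k factorisation rank K the program came from.
#' @param factor_index zero-based factor index within that rank.
#' @param genes ordered character vector of top genes.
#' @param weights numeric basis coefficients for `genes`, non-increasing.
#' @return Object of class `nmf_program`.
#' @export
nmf_program <- function(sample_id, rank_k, factor_index, genes, weights) {
  stopifnot(length(genes) == length(weights), !anyDuplicated(genes),
            all(weights >= 0), !is.unsorted(rev(weights)))
  structure(list(sample_id = sample_id, rank_k = as.integer(rank_k),
                 factor_index = as.integer(factor_index),
                 genes = genes, weights = setNames(weights, genes)),
            class = "nmf_program")
}

#' @method print nmf_program
#' @export
print.nmf_program <- function(x, ...) {
  cat(sprintf("<nmf_program> %s K=%d factor=%d: %d genes (top: %s)\n",
              x$sample_id, x$rank_k, x$factor_index, length(x$genes),
              paste(head(x$genes, 3), collapse = ", ")))
  invisible(x)
}

program_key <- function(p)
  sprintf("%s|K%d|f%d", p$sample_id, p$rank_k, p$factor_index)

# NNDSVDa initialization (Boutsidis & Gallopoulos): SVD-based, deterministic,
# zeros replaced by the matrix mean to avoid multiplicative-update locking.
nndsvda_init <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg) {
      W[, j] <- sqrt(s$d[j] * npos) * up / max(sqrt(sum(up^2)), 1e-12)
      H[j, ] <- sqrt(s$d[j] * npos) * vp / max(sqrt(sum(vp^2)), 1e-12)
    } else {
      W[, j] <- sqrt(s$d[j] * nneg) * un / max(sqrt(sum(un^2)), 1e-12)
      H[j, ] <- sqrt(s$d[j] * nneg) * vn / max(sqrt(sum(vn^2)), 1e-12)
    }
  }
  avg <- mean(A)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

#' Non-negative matrix factorisation of one sample
#'
#' Factorises the normalized layer as `A ~ W H` with multiplicative
#' Frobenius updates from a deterministic NNDSVDa initialization, so a
#' given matrix and rank always produce the same factors.
#'
#' @param m a [sample_matrix()] with the normalized layer filled.
#' @param k factorisation rank, `1 <= k <= min(dim)`.
#' @param seed kept for interface stability; the deterministic
#'   initialization makes the result seed-independent.
#' @param max_iter,tol update budget and relative-error convergence
#'   tolerance.
#' @return list with `basis` (genes x k), `loadings` (k x cells),
#'   `frobenius_error`, `iterations`.
#' @export
factorize <- function(m, k, seed = 1L, max_iter = 500, tol = 1e-4) {
  stopifnot(inherits(m, "sample_matrix"))
  if (is.null(m$normalized))
    stop("normalized layer missing; run normalize_for_nmf() first")
  A <- m$normalized
  if (k < 1 || k > min(dim(A)))
    stop(sprintf("k=%d outside [1, %d]", k, min(dim(A))))
  if (min(A) < 0) stop("normalized layer has negative entries")
  init <- nndsvda_init(A, k)
  fit <- .nmf_mu_cpp(A, init$W, init$H, as.integer(max_iter), tol)
  dimnames(fit$W) <- list(rownames(A), paste0("f", seq_len(k) - 1L))
  dimnames(fit$H) <- list(paste0("f", seq_len(k) - 1L), colnames(A))
  list(basis = fit$W, loadings = fit$H,
       frobenius_error = fit$frobenius_error, iterations = fit$iterations)
}

#' Extract top-gene programs across a range of NMF ranks
#'
#' Runs [factorize()] for every rank in `k_range` and turns each factor
#' into an [nmf_program()] of its `genes_per_program` top-weighted genes
#' (ties broken by gene id). The program count is the deterministic
#' `sum(k_range)` whatever the data: K = 4..9 gives 39 programs per sample.
#'
#' @param m a normalized [sample_matrix()].
#' @param k_range integer vector of ranks (default 4:9).
#' @param genes_per_program signature size (default 50).
#' @param seed forwarded to [factorize()].
#' @param max_iter,tol forwarded to [factorize()].
#' @return list of [nmf_program()] objects, ordered by rank then factor.
#' @export
extract_programs <- function(m, k_range = 4:9, genes_per_program = 50,
                             seed = 1L, max_iter = 500, tol = 1e-4) {
  stopifnot(inherits(m, "sample_matrix"), length(k_range) >= 1)
  if (genes_per_program > nrow(m$counts))
    stop(sprintf("genes_per_program (%d) exceeds gene count (%d)",
                 genes_per_program, nrow(m$counts)))
  ks <- sort(unique(as.integer(k_range)))
  out <- vector("list", sum(ks))
  i <- 0L
  for (k in ks) {
    fit <- factorize(m, k, seed = seed, max_iter = max_iter, tol = tol)
    for (j in seq_len(k)) {
      w <- fit$basis[, j]
      ord <- order(-w, names(w))[seq_len(genes_per_program)]
      i <- i + 1L
      out[[i]] <- nmf_program(m$sample_id, k, j - 1L,
                              genes = names(w)[ord], weights = w[ord])
    }
  }
  out
}
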