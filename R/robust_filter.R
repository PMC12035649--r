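#' A pool of NMF programs with a per-sample index
#'
#' @param programs list of [nmf_program()]; (sample, rank, factor) keys must
#'   be unique.
#' @return Object of class `program_set`.
#' @export
program_set <- function(programs) {
  stopifnot(is.list(programs),
            all(vapply(programs, inherits, TRUE, "nmf_program")))
  keys <- vapply(programs, program_key, "")
  if (anyDuplicated(keys))
    stop("duplicate (sample_id, rank_k, factor_index) keys")
  sids <- vapply(programs, `[[`, "", "sample_id")
  structure(list(programs = programs,
                 index = split(seq_along(programs), sids)),
            class = "program_set")
}

#' @export
length.program_set <- function(x) length(x$programs)

#' @method print program_set
#' @export
print.program_set <- function(x, ...) {
  cat(sprintf("<program_set> %d programs across %d samples\n",
              length(x$programs), length(x$index)))
  invisible(x)
}

#' Shared-gene count between two programs
#'
#' Percent thresholds in the robustness criteria are all expressed against
#' the fixed program size of 50 genes: 70% = 35 shared genes, 20% = 10,
#' 30% = 15.
#'
#' @param a,b [nmf_program()] objects.
#' @return integer `|genes(a) n genes(b)|`; symmetric.
#' @export
overlap <- function(a, b) {
  stopifnot(length(a$genes) > 0, length(b$genes) > 0)
  length(intersect(a$genes, b$genes))
}

# sample-wise deterministic ordering key used by several tie-breaks
program_order_key <- function(programs)
  order(vapply(programs, `[[`, "", "sample_id"),
        vapply(programs, `[[`, 1L, "rank_k"),
        vapply(programs, `[[`, 1L, "factor_index"))

#' Cross-rank robustness within a sample
#'
#' A program is intra-sample robust when some program of a *different* rank
#' K in the same sample shares at least `min_overlap` genes with it
#' (70% of 50 by default).
#'
#' @param p an [nmf_program()] belonging to `pool`.
#' @param pool a [program_set()].
#' @param min_overlap shared-gene threshold (default 35).
#' @return logical.
#' @export
passes_intra_sample <- function(p, pool, min_overlap = 35) {
  stopifnot(inherits(pool, "program_set"))
  for (i in pool$index[[p$sample_id]]) {
    q <- pool$programs[[i]]
    if (q$rank_k != p$rank_k && overlap(p, q) >= min_overlap) return(TRUE)
  }
  FALSE
}

#' Cross-sample robustness
#'
#' A program is inter-sample robust when some program of a *different*
#' sample shares at least `min_overlap` genes with it (20% of 50 by
#' default).
#'
#' @inheritParams passes_intra_sample
#' @param min_overlap shared-gene threshold (default 10).
#' @return logical.
#' @export
passes_inter_sample <- function(p, pool, min_overlap = 10) {
  stopifnot(inherits(pool, "program_set"))
  if (length(pool$index) < 2L)
    stop("inter-sample criterion undefined on a single-sample pool")
  for (sid in names(pool$index)) {
    if (sid == p$sample_id) next
    for (i in pool$index[[sid]])
      if (overlap(p, pool$programs[[i]]) >= min_overlap) return(TRUE)
  }
  FALSE
}

# max overlap of p with programs of other samples in `programs`
max_inter_sample_overlap <- function(p, programs) {
  best <- 0L
  for (q in programs)
    if (q$sample_id != p$sample_id) best <- max(best, overlap(p, q))
  best
}

#' Remove redundant programs within each sample
#'
#' Greedy non-redundancy pass: within each sample, candidates are processed
#' in order of decreasing maximal inter-sample overlap (ties: lower rank_k,
#' then factor_index) and a candidate sharing more than `max_overlap` genes
#' (30% of 50 by default) with an already-retained program of the same
#' sample is dropped. Prioritising cross-sample support keeps the more
#' robust of two redundant programs.
#'
#' @param kept list of [nmf_program()] that already pass the intra- and
#'   inter-sample criteria.
#' @param max_overlap largest tolerated shared-gene count between retained
#'   same-sample programs (default 15).
#' @return filtered list of [nmf_program()].
#' @export
deduplicate_within_sample <- function(kept, max_overlap = 15) {
  if (length(kept) == 0L) return(kept)
  support <- vapply(kept, max_inter_sample_overlap, 0L, programs = kept)
  ord <- order(-support,
               vapply(kept, `[[`, 1L, "rank_k"),
               vapply(kept, `[[`, 1L, "factor_index"))
  retained <- list()
  for (i in ord) {
    p <- kept[[i]]
    clash <- any(vapply(retained, function(q)
      q$sample_id == p$sample_id && overlap(p, q) > max_overlap, TRUE))
    if (!clash) retained[[length(retained) + 1L]] <- p
  }
  retained[program_order_key(retained)]
}

#' Select robust NMF programs
#'
#' The composite three-criterion filter: keep programs that (1) recur
#' across ranks within their sample (>= `min_intra` shared genes), (2) have
#' a counterpart in another sample (>= `min_inter`), then (3) drop
#' within-sample redundancy (> `max_dedup` shared genes) greedily via
#' [deduplicate_within_sample()]. Idempotent; raising any threshold can
#' only shrink the output.
#'
#' @param pool a multi-sample [program_set()].
#' @param min_intra,min_inter,max_dedup shared-gene thresholds
#'   (defaults 35 / 10 / 15, i.e. 70% / 20% / 30% of a 50-gene program).
#' The returned set keeps the candidate pool it was filtered from as an
#' `evidence` attribute: the recurrence criteria are statements about the
#' full program pool, so re-filtering a robust set re-evaluates them
#' against that original evidence (making the filter idempotent) rather
#' than against the thinned-out survivors, whose cross-rank twins were
#' removed by the redundancy pass.
#'
#' @return a [program_set()] of robust programs, with an `audit` attribute
#'   recording each input program's per-criterion outcome and an
#'   `evidence` attribute holding the candidate pool.
#' @export
select_robust <- function(pool, min_intra = 35, min_inter = 10,
                          max_dedup = 15) {
  stopifnot(inherits(pool, "program_set"))
  evidence <- attr(pool, "evidence")
  if (is.null(evidence)) evidence <- pool
  intra <- vapply(pool$programs, passes_intra_sample, TRUE,
                  pool = evidence, min_overlap = min_intra)
  inter <- vapply(pool$programs, passes_inter_sample, TRUE,
                  pool = evidence, min_overlap = min_inter)
  kept <- pool$programs[intra & inter]
  final <- deduplicate_within_sample(kept, max_overlap = max_dedup)
  final_keys <- vapply(final, program_key, "")
  audit <- data.frame(
    program = vapply(pool$programs, program_key, ""),
    pass_intra = intra, pass_inter = inter,
    retained = vapply(pool$programs, program_key, "") %in% final_keys)
  out <- program_set(final)
  attr(out, "audit") <- audit
  attr(out, "evidence") <- evidence
  out
}
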