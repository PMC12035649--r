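#' Jaccard index between two gene sets
#'
#' @param a,b non-empty character vectors of gene ids.
#' @return `|A n B| / |A u B|`, in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("jaccard undefined for empty gene sets")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' A consensus meta-program
#'
#' A 50-gene consensus signature built from a cluster of robust NMF
#' programs, together with its members and the founding program.
#'
#' @param mp_id label.
#' @param genes ordered character vector, exactly `size` genes.
#' @param members list of member [nmf_program()]s.
#' @param founder the founding [nmf_program()].
#' @param audit optional data frame logging each admission.
#' @param size required signature size (default 50).
#' @return Object of class `meta_program`.
#' @export
meta_program <- function(mp_id, genes, members, founder, audit = NULL,
                         size = 50) {
  stopifnot(length(genes) == size, !anyDuplicated(genes),
            length(members) > 0L)
  structure(list(mp_id = mp_id, genes = genes, members = members,
                 founder = founder, audit = audit),
            class = "meta_program")
}

#' @method print meta_program
#' @export
print.meta_program <- function(x, ...) {
  cat(sprintf("<meta_program> %s: %d genes, %d member programs (founder %s)\n",
              x$mp_id, length(x$genes), length(x$members),
              program_key(x$founder)))
  invisible(x)
}

#' Find the next cluster founder
#'
#' A program qualifies as a founder when more than `min_cases` other pool
#' programs each share at least `founder_min_overlap` genes with it; among
#' qualifying programs the one with the most such supporters wins (ties:
#' larger mean overlap with supporters, then sample/rank/factor order).
#'
#' @param pool a [program_set()].
#' @param founder_min_overlap pairwise shared-gene threshold for a
#'   supporter (default 8).
#' @param min_cases a founder needs strictly more than this many
#'   supporters (default 5).
#' @return the founding [nmf_program()], or `NULL` when no program
#'   qualifies.
#' @export
find_founder <- function(pool, founder_min_overlap = 8, min_cases = 5) {
  stopifnot(inherits(pool, "program_set"))
  ps <- pool$programs
  n <- length(ps)
  if (n == 0L) return(NULL)
  n_sup <- integer(n); mean_ov <- numeric(n)
  for (i in seq_len(n)) {
    ov <- vapply(ps[-i], overlap, 0L, a = ps[[i]])
    sup <- ov[ov >= founder_min_overlap]
    n_sup[i] <- length(sup)
    mean_ov[i] <- if (length(sup)) mean(sup) else 0
  }
  cand <- which(n_sup > min_cases)
  if (length(cand) == 0L) return(NULL)
  ord <- program_order_key(ps[cand])
  cand <- cand[ord]                       # deterministic final tie-break
  cand <- cand[order(-n_sup[cand], -mean_ov[cand])]
  ps[[cand[1]]]
}

#' Complete a meta-program signature to a fixed size
#'
#' Ranks the union of member genes by how many members carry the gene
#' (descending), then by mean NMF weight across the members carrying it
#' (descending), then by gene id, and returns the top `size`: the cluster's
#' common genes first, completed by the highest-scoring remainder.
#'
#' @param members non-empty list of [nmf_program()].
#' @param size signature size (default 50).
#' @return ordered character vector of `size` genes.
#' @export
complete_mp <- function(members, size = 50) {
  stopifnot(length(members) > 0L)
  all_genes <- unlist(lapply(members, `[[`, "genes"))
  freq <- table(all_genes)
  u <- names(freq)
  if (length(u) < size)
    stop(sprintf("union of member genes (%d) smaller than MP size (%d): short by %d",
                 length(u), size, size - length(u)))
  wsum <- setNames(numeric(length(u)), u)
  for (m in members) wsum[m$genes] <- wsum[m$genes] + m$weights
  mean_w <- wsum / as.numeric(freq[u])
  u[order(-as.numeric(freq[u]), -mean_w, u)][seq_len(size)]
}

#' Grow one meta-program cluster from a founder
#'
#' Seeds the cluster with the founder and its highest-overlap partner,
#' defines the MP via [complete_mp()], then repeatedly admits the remaining
#' pool program sharing the most genes with the *current* MP signature
#' (requiring at least `accrete_min_overlap`; ties broken by
#' sample/rank/factor order), recomputing the signature after every
#' admission.
#'
#' @param founder an [nmf_program()] contained in `pool`.
#' @param pool a [program_set()].
#' @param accrete_min_overlap admission threshold against the current MP
#'   gene set (default 10).
#' @param founder_min_overlap minimum founder/partner overlap (default 8).
#' @param size MP signature size (default 50).
#' @param mp_id label for the resulting MP.
#' @return list with `mp` (a [meta_program()]) and `remaining` (a
#'   [program_set()] of the unconsumed pool).
#' @export
build_cluster <- function(founder, pool, accrete_min_overlap = 10,
                          founder_min_overlap = 8, size = 50,
                          mp_id = "MP1") {
  stopifnot(inherits(pool, "program_set"))
  keys <- vapply(pool$programs, program_key, "")
  fi <- match(program_key(founder), keys)
  if (is.na(fi)) stop("founder not in pool")
  rest <- pool$programs[-fi]
  if (length(rest) == 0L) stop("founder has no potential partner in pool")
  ov <- vapply(rest, overlap, 0L, a = founder)
  ord <- program_order_key(rest)
  best <- ord[which.max(ov[ord])]
  if (ov[best] < founder_min_overlap)
    stop(sprintf("founder's best partner shares only %d genes (< %d)",
                 ov[best], founder_min_overlap))
  members <- list(founder, rest[[best]])
  audit <- data.frame(step = 1:2,
                      program = c(program_key(founder),
                                  program_key(rest[[best]])),
                      overlap_at_admission = c(NA_integer_, ov[best]))
  rest <- rest[-best]
  mp_genes <- complete_mp(members, size = size)
  repeat {
    if (length(rest) == 0L) break
    ov <- vapply(rest, function(p) length(intersect(p$genes, mp_genes)),
                 0L)
    ord <- program_order_key(rest)
    best <- ord[which.max(ov[ord])]
    if (ov[best] < accrete_min_overlap) break
    members[[length(members) + 1L]] <- rest[[best]]
    audit <- rbind(audit, data.frame(step = length(members),
                                     program = program_key(rest[[best]]),
                                     overlap_at_admission = ov[best]))
    rest <- rest[-best]
    mp_genes <- complete_mp(members, size = size)
  }
  list(mp = meta_program(mp_id, mp_genes, members, founder, audit,
                         size = size),
       remaining = if (length(rest)) program_set(rest)
                   else structure(list(programs = list(), index = list()),
                                  class = "program_set"))
}

#' Cluster all robust programs into meta-programs
#'
#' Repeats [find_founder()] / [build_cluster()] until no founder remains.
#' Every program ends up in exactly one MP or in the unassigned leftover;
#' member sets of distinct MPs are disjoint by construction (admitted
#' programs are removed from the pool and never revisited).
#'
#' @param pool a [program_set()], normally the output of [select_robust()].
#' @param founder_min_overlap,min_cases founder rule (defaults 8 and 5).
#' @param accrete_min_overlap admission threshold (default 10).
#' @param size MP signature size (default 50).
#' @return list with `mps` (list of [meta_program()], creation order) and
#'   `unassigned` (list of leftover [nmf_program()]).
#' @export
cluster_all <- function(pool, founder_min_overlap = 8, min_cases = 5,
                        accrete_min_overlap = 10, size = 50) {
  stopifnot(inherits(pool, "program_set"))
  mps <- list()
  repeat {
    f <- find_founder(pool, founder_min_overlap = founder_min_overlap,
                      min_cases = min_cases)
    if (is.null(f)) break
    res <- build_cluster(f, pool,
                         accrete_min_overlap = accrete_min_overlap,
                         founder_min_overlap = founder_min_overlap,
                         size = size,
                         mp_id = sprintf("MP%d", length(mps) + 1L))
    mps[[length(mps) + 1L]] <- res$mp
    pool <- res$remaining
    if (length(pool$programs) == 0L) break
  }
  list(mps = mps, unassigned = pool$programs)
}
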