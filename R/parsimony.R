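## Backward elimination of redundant members, the greedy-mode insertion
## phase, and aggregation of parsimony models into the candidate gene set.

#' Redundancy test for one member of a seed feature set
#'
#' A member `f` of a set `members` is redundant when the class carries no
#' information about `f` beyond what the remaining members already provide:
#' the plug-in conditional mutual information
#' \eqn{CMI(f, C \mid members \setminus f)} is zero (up to `tol`, which
#' only absorbs floating-point noise — on integer counts the plug-in
#' estimate is exactly zero when the counts factorize within every
#' stratum).
#'
#' @param f gene id, a member of `members`.
#' @param members character vector of gene ids (the seed set), length >= 2.
#' @param codes discretized expression matrix.
#' @param y binary class vector.
#' @param tol non-negative tolerance (default `1e-12`).
#' @return logical.
#' @export
is_redundant <- function(f, members, codes, y, tol = 1e-12) {
  if (!f %in% members) stop("'", f, "' is not a member of the set")
  rest <- setdiff(members, f)
  if (!length(rest)) stop("conditioning set is empty (set of size < 2)")
  conditional_mutual_information(codes[, f], y,
                                 codes[, rest, drop = FALSE]) <= tol
}

#' Backward phase: prune seed feature sets into parsimony models
#'
#' Applies first-seat-last-check elimination to every seed set: non-seed
#' members are tested in ascending relevance order (least relevant first)
#' and the seed is tested last; a member found redundant is removed
#' immediately and permanently; if the seed itself is removed the whole set
#' is discarded; surviving sets must keep at least two members. The pass is
#' idempotent — re-running it on its own output changes nothing.
#'
#' @param g_pre named list of seed sets from [forward_phase()] (seed first,
#'   members ordered by decreasing relevance).
#' @inheritParams is_redundant
#' @return named list of surviving parsimony models (same layout).
#' @export
backward_phase <- function(g_pre, codes, y, tol = 1e-12) {
  out <- list()
  for (set in g_pre) {
    seed <- set[1L]
    current <- set
    ## ascending relevance = reverse of the stored member order; seed last
    for (f in c(rev(set[-1L]), seed)) {
      if (!f %in% current) next
      if (length(current) < 2L) break
      if (is_redundant(f, current, codes, y, tol)) {
        if (f == seed) { current <- character(0); break }
        current <- setdiff(current, f)
      }
    }
    if (length(current) >= 2L) out[[seed]] <- current
  }
  out
}

#' Insertion phase (greedy mode)
#'
#' Between the two greedy-mode backward runs, features that survive inside
#' several seed sets are promoted: for every feature `f_j` occurring in at
#' least two surviving sets, a set led by `f_j` is created (if absent) and
#' the seeds of the sets containing `f_j` are inserted into it, unless
#' already present. Member order is re-established by decreasing relevance.
#' With no cross-set sharing the collection is returned unchanged.
#'
#' @param sets named list of surviving seed sets (seed first).
#' @param r1 named numeric vector of per-gene relevance values.
#' @return named list of seed sets, ordered by seed relevance descending.
#' @export
insertion_phase <- function(sets, r1) {
  if (!length(sets)) return(sets)
  occ <- table(unlist(sets, use.names = FALSE))
  shared <- names(occ)[occ >= 2L]
  for (j in shared) {
    donors <- names(sets)[vapply(sets, function(m) j %in% m[-1L], NA)]
    if (!length(donors)) next
    if (is.null(sets[[j]])) sets[[j]] <- j
    for (s in donors)
      if (!s %in% sets[[j]]) sets[[j]] <- c(sets[[j]], s)
    if (length(sets[[j]]) < 2L) sets[[j]] <- NULL
  }
  sets <- lapply(names(sets), function(s) {
    mem <- setdiff(sets[[s]], s)
    c(s, mem[order(-r1[mem], mem)])
  })
  names(sets) <- vapply(sets, `[`, "", 1L)
  seeds <- names(sets)
  sets[order(-r1[seeds], seeds)]
}

#' Aggregate parsimony models into the candidate gene set
#'
#' Models are dissolved in order of decreasing seed relevance (seed gene id
#' breaking ties); their members are concatenated and de-duplicated keeping
#' the first occurrence, recording for each gene the index of the first
#' model that contributed it.
#'
#' @param models named list of parsimony models (seed first).
#' @param r1 named numeric vector of per-gene relevance values.
#' @return data frame with columns `rank`, `gene_id`, `seed_set_index`,
#'   `r1`; zero rows (with a warning) for an empty model collection.
#' @export
aggregate_candidates <- function(models, r1) {
  if (!length(models)) {
    warning("empty model collection; empty candidate set")
    return(data.frame(rank = integer(0), gene_id = character(0),
                      seed_set_index = integer(0), r1 = numeric(0)))
  }
  seeds <- names(models)
  models <- models[order(-r1[seeds], seeds)]
  genes <- unlist(models, use.names = FALSE)
  src <- rep.int(seq_along(models), lengths(models))
  keep <- !duplicated(genes)
  data.frame(rank = seq_len(sum(keep)), gene_id = genes[keep],
             seed_set_index = src[keep], r1 = unname(r1[genes[keep]]),
             stringsAsFactors = FALSE)
}
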