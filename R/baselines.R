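## Simplified reference filters: mRMR (MI-difference form), CMIM (pairwise
## conditioning), FCBF (approximate-Markov-blanket elimination). These are
## deterministic (all ties broken by gene id, ascending) and exist so the
## evaluation and stability harnesses can be exercised end-to-end; they do
## not claim bit-compatibility with the original authors' implementations.

first_max <- function(score, ids) {
  sort(ids[score == max(score)])[1L]
}

#' mRMR gene selection (mutual-information difference criterion)
#'
#' Greedy forward selection maximizing relevance minus mean redundancy:
#' the first gene maximizes \eqn{MI(f, C)}; each further step picks the
#' gene maximizing \eqn{MI(f, C) - \frac{1}{|S|}\sum_{s \in S} MI(f, s)}.
#'
#' @param codes discretized expression matrix (samples x genes, named
#'   columns).
#' @param y binary class vector.
#' @param budget number of genes to return (truncated to the number of
#'   genes available, with a warning).
#' @return data frame with columns `gene_id` and `score` (the criterion
#'   value at selection time), one row per selection step.
#' @export
mrmr_select <- function(codes, y, budget) {
  genes <- colnames(codes)
  if (budget > length(genes)) {
    warning("budget exceeds the number of genes; truncated")
    budget <- length(genes)
  }
  if (budget <= 0)
    return(data.frame(gene_id = character(0), score = numeric(0)))
  rel <- vapply(genes, function(g) mutual_information(codes[, g], y), 0)
  sel <- character(0); val <- numeric(0)
  red_sum <- stats::setNames(numeric(length(genes)), genes)
  for (step in seq_len(budget)) {
    avail <- setdiff(genes, sel)
    score <- if (!length(sel)) rel[avail]
             else rel[avail] - red_sum[avail] / length(sel)
    g <- first_max(score, avail)
    sel <- c(sel, g); val <- c(val, score[[g]])
    if (step < budget) {
      avail2 <- setdiff(genes, sel)
      red_sum[avail2] <- red_sum[avail2] + vapply(avail2, function(f)
        mutual_information(codes[, f], codes[, g]), 0)
    }
  }
  data.frame(gene_id = sel, score = unname(val), stringsAsFactors = FALSE)
}

#' CMIM gene selection (conditional mutual information maximization)
#'
#' Greedy forward selection with pairwise conditioning only: the first
#' gene maximizes \eqn{MI(f, C)}; each further step picks the gene
#' maximizing \eqn{\min_{s \in S} CMI(f, C \mid s)}. A duplicate of an
#' already-selected gene scores exactly zero.
#'
#' @inheritParams mrmr_select
#' @return data frame with columns `gene_id` and `score`.
#' @export
cmim_select <- function(codes, y, budget) {
  genes <- colnames(codes)
  if (budget > length(genes)) {
    warning("budget exceeds the number of genes; truncated")
    budget <- length(genes)
  }
  if (budget <= 0)
    return(data.frame(gene_id = character(0), score = numeric(0)))
  rel <- vapply(genes, function(g) mutual_information(codes[, g], y), 0)
  minscore <- rel                          # running min over selected s
  sel <- character(0); val <- numeric(0)
  for (step in seq_len(budget)) {
    avail <- setdiff(genes, sel)
    g <- first_max(minscore[avail], avail)
    sel <- c(sel, g); val <- c(val, minscore[[g]])
    if (step < budget) {
      avail2 <- setdiff(genes, sel)
      minscore[avail2] <- pmin(minscore[avail2], vapply(avail2, function(f)
        conditional_mutual_information(codes[, f], y, codes[, g]), 0))
    }
  }
  data.frame(gene_id = sel, score = unname(val), stringsAsFactors = FALSE)
}

#' FCBF gene selection (approximate Markov blanket elimination)
#'
#' Ranks genes by \eqn{SU(f, C)} descending (keeping those at or above
#' `su_threshold`), then walks the ranking removing every later gene
#' \eqn{f_j} for which an earlier surviving gene \eqn{f_i} satisfies
#' \eqn{SU(f_i, f_j) \ge SU(f_j, C)} — the approximate-Markov-blanket
#' rule. The method may therefore return fewer genes than any requested
#' budget; exact duplicates keep only the higher-ranked copy.
#'
#' @inheritParams mrmr_select
#' @param su_threshold minimum class relevance to enter the ranking
#'   (default 0, i.e. everything enters).
#' @return data frame with columns `gene_id` and `score` (`SU(f, C)`),
#'   surviving genes in rank order.
#' @export
fcbf_select <- function(codes, y, su_threshold = 0) {
  genes <- colnames(codes)
  rel <- vapply(genes, function(g) symmetrical_uncertainty(codes[, g], y), 0)
  keep <- rel >= su_threshold
  ord <- order(-rel[keep], genes[keep])
  ranked <- genes[keep][ord]
  alive <- rep(TRUE, length(ranked))
  for (a in seq_along(ranked)) {
    if (!alive[a]) next
    if (a == length(ranked)) break
    for (b in (a + 1L):length(ranked)) {
      if (!alive[b]) next
      su_ij <- symmetrical_uncertainty(codes[, ranked[a]], codes[, ranked[b]])
      if (su_ij >= rel[[ranked[b]]]) alive[b] <- FALSE
    }
  }
  surv <- ranked[alive]
  data.frame(gene_id = surv, score = unname(rel[surv]),
             stringsAsFactors = FALSE)
}
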