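## Stability indices for systems of gene lists and the leave-one-out
## stability experiment.

#' Jaccard index of two gene sets
#'
#' \eqn{|G_i \cap G_j| / |G_i \cup G_j|}. Two empty sets are identical by
#' convention and score 1 (with a message).
#' @param g_i,g_j character vectors of gene ids.
#' @export
jaccard_index <- function(g_i, g_j) {
  g_i <- unique(g_i); g_j <- unique(g_j)
  u <- length(union(g_i, g_j))
  if (u == 0L) {
    message("both gene lists empty; Jaccard index defined as 1")
    return(1)
  }
  length(intersect(g_i, g_j)) / u
}

#' Overall Jaccard stability of a system of gene lists
#'
#' Mean Jaccard index over all \eqn{l(l-1)/2} unordered pairs of lists.
#' @param lists list of at least two character vectors.
#' @export
overall_jaccard <- function(lists) {
  l <- length(lists)
  if (l < 2L) stop("need at least two gene lists")
  s <- 0
  for (i in seq_len(l - 1L))
    for (j in (i + 1L):l)
      s <- s + jaccard_index(lists[[i]], lists[[j]])
  s / (l * (l - 1) / 2)
}

#' Relative weighted consistency of a system of gene lists
#'
#' Occurrence-count consistency index that corrects the Jaccard
#' list-size bias. With \eqn{N} the total number of gene occurrences over
#' the \eqn{l} lists, \eqn{R_f} the per-gene occurrence count,
#' \eqn{Q = N \bmod |F|} and \eqn{q = N \bmod l}:
#' \deqn{S_{RWC} = \frac{|F|(N - Q + \sum_f R_f(R_f - 1)) - N^2 + Q^2}
#'                      {|F|(q^2 + l(N - q) - Q) - N^2 + Q^2}.}
#' Identical lists score 1; fully disjoint single-occurrence systems score 0.
#'
#' @param lists list of at least two character vectors of gene ids.
#' @param universe_size size of the feature universe \eqn{|F|} (must be at
#'   least the number of distinct genes appearing in the lists).
#' @export
relative_weighted_consistency <- function(lists, universe_size) {
  l <- length(lists)
  if (l < 2L) stop("need at least two gene lists")
  lists <- lapply(lists, unique)
  genes <- unlist(lists, use.names = FALSE)
  if (length(unique(genes)) > universe_size)
    stop("lists contain more distinct genes than 'universe_size'")
  Fsz <- universe_size
  N <- length(genes)
  Rf <- table(genes)
  Q <- N %% Fsz
  q <- N %% l
  num <- Fsz * (N - Q + sum(Rf * (Rf - 1))) - N^2 + Q^2
  den <- Fsz * (q^2 + l * (N - q) - Q) - N^2 + Q^2
  if (den == 0)
    stop("degenerate list system (zero denominator): N = ", N,
         ", |F| = ", Fsz, ", l = ", l)
  num / den
}

#' Leave-one-out stability experiment
#'
#' Builds the n leave-one-out subsamples of the data, runs the chosen gene
#' selector on each, and scores the resulting system of gene lists with
#' the overall Jaccard stability and the relative weighted consistency.
#' The iRDA filter fixes its own list cardinality; the reference filters
#' are each given a per-fold budget equal to the iRDA list size on that
#' fold (supplied via `budgets`, or computed by running iRDA first). FCBF
#' may return fewer genes than its budget; shorter lists are accepted.
#'
#' @param x expression matrix (samples x genes) or a dataset with `$x`,`$y`.
#' @param y binary class vector.
#' @param selector `"irda"`, `"mrmr"`, `"cmim"` or `"fcbf"`.
#' @param budgets optional integer vector (length n) of per-fold gene
#'   budgets for the reference filters; computed from per-fold iRDA runs
#'   when omitted.
#' @param ... further arguments passed to [irda()] (e.g. `mode`, `K`, `L`).
#' @return object of class `"irda_stability"`: list with `lists` (n gene
#'   lists), `sizes`, `s_ji`, `s_rwc`, `selector`, `universe_size`.
#' @export
loo_stability <- function(x, y = NULL,
                          selector = c("irda", "mrmr", "cmim", "fcbf"),
                          budgets = NULL, ...) {
  selector <- match.arg(selector)
  if (is.list(x) && !is.null(x$x)) { if (is.null(y)) y <- x$y; x <- x$x }
  x <- as.matrix(x)
  y <- encode_labels(y)
  n <- nrow(x)
  if (selector != "irda" && is.null(budgets)) {
    budgets <- vapply(seq_len(n), function(i)
      nrow(suppressWarnings(irda(x[-i, , drop = FALSE], y[-i], ...))$candidates),
      0L)
  }
  lists <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    yi <- y[-i]
    if (selector == "irda") {
      lists[[i]] <- suppressWarnings(irda(xi, yi, ...))$candidates$gene_id
    } else {
      codes <- discretize(xi)
      b <- budgets[i]
      lists[[i]] <- switch(selector,
        mrmr = mrmr_select(codes, yi, b)$gene_id,
        cmim = cmim_select(codes, yi, b)$gene_id,
        fcbf = utils::head(fcbf_select(codes, yi)$gene_id, b))
      if (selector == "fcbf" && length(lists[[i]]) < b)
        message("fold ", i, ": FCBF returned ", length(lists[[i]]),
                " of ", b, " requested genes")
    }
  }
  structure(list(lists = lists, sizes = lengths(lists),
                 s_ji = overall_jaccard(lists),
                 s_rwc = relative_weighted_consistency(lists, ncol(x)),
                 selector = selector, universe_size = ncol(x)),
            class = "irda_stability")
}

#' @export
print.irda_stability <- function(x, ...) {
  cat(sprintf("LOO stability of '%s' over %d folds: S_JI = %.4f, S_RWC = %.4f\n",
              x$selector, length(x$lists), x$s_ji, x$s_rwc))
  cat("  list sizes:", paste(range(x$sizes), collapse = "-"), "\n")
  invisible(x)
}
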