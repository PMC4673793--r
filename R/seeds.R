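## Seed discovery: epsilon estimation and the forward phase.
##
## Both stages walk the same enumeration of candidate feature-pairs:
## the outer loop runs over Omega_1 in rank order (seed side f_i), the
## inner loop over Omega_1..Omega_{K-1} in rank order (partner side f_j),
## skipping partners ranked at or above the seed inside Omega_1 so each
## unordered pair is visited once. The last group Omega_K is treated as
## irrelevant and excluded. Joint-SU values are cached per pair and shared
## between the two stages.

pair_key <- function(i, j) paste(i, j, sep = "\r")

## Enumerate candidate pairs in the canonical order. Returns a data frame
## of (i, j) gene ids with i the Omega_1 seed.
enumerate_pairs <- function(partition) {
  K <- partition$K
  omega1 <- partition$groups[[1L]]
  pool <- unlist(partition$groups[seq_len(max(K - 1L, 1L))], use.names = FALSE)
  n1 <- length(omega1)
  np <- length(pool)
  ## Omega_1 genes head the pool, so skipping partners ranked at or above
  ## the seed inside Omega_1 leaves exactly the partners below the seed:
  ## seed rank a pairs with pool positions (a+1)..np.
  if (n1 == 0L || np < 2L)
    return(data.frame(i = character(0), j = character(0)))
  lens <- np - seq_len(n1)
  a <- rep.int(seq_len(n1), lens)
  b <- sequence(lens) + a
  data.frame(i = omega1[a], j = pool[b], stringsAsFactors = FALSE)
}

## Cached joint SU of a pair against the class.
pair_r2 <- function(i, j, codes, y, cache = NULL) {
  if (!is.null(cache)) {
    k <- pair_key(min(i, j), max(i, j))
    v <- cache[[k]]
    if (!is.null(v)) return(v)
    v <- joint_symmetrical_uncertainty(codes[, i], codes[, j], y)
    cache[[k]] <- v
    return(v)
  }
  joint_symmetrical_uncertainty(codes[, i], codes[, j], y)
}

#' Estimate the epsilon threshold for strongly relevant feature-pairs
#'
#' A pair \eqn{(f_i, f_j)} (with \eqn{f_i} ahead of \eqn{f_j} in partition
#' order) is a *positive joint feature-pair* when its joint class
#' correlation exceeds each member's individual class correlation and the
#' weaker member's class correlation exceeds the pair's mutual correlation:
#' \eqn{R(f_{ij},C) > R(f_i,C)}, \eqn{R(f_{ij},C) > R(f_j,C)} and
#' \eqn{\min(R(f_i,C), R(f_j,C)) > R(f_i,f_j)}. `rule = "literal"` keeps
#' only the two comparisons \eqn{R(f_{ij},C) > R(f_i,C)} and
#' \eqn{R(f_j,C) > R(f_i,f_j)}. The threshold \eqn{\varepsilon} is the mean
#' joint correlation of the first `L` positive pairs in enumeration order.
#'
#' @param partition an `"irda_partition"` from [build_partition()].
#' @param codes discretized expression matrix (samples x genes).
#' @param y binary class vector.
#' @param L number of positive pairs to average (default 100). If fewer are
#'   found, all of them are used (with a message); zero positive pairs is
#'   an error.
#' @param rule `"chain"` (default, three conditions) or `"literal"` (two).
#' @param cache optional environment used to memoize joint-SU values.
#' @return object of class `"irda_epsilon"`: list with `value`,
#'   `pairs_used`, `pairs` (the contributing pairs and their joint SU) and
#'   `rule`.
#' @export
estimate_epsilon <- function(partition, codes, y, L = 100,
                             rule = c("chain", "literal"), cache = NULL) {
  rule <- match.arg(rule)
  if (L < 1) stop("'L' must be positive")
  r1 <- stats::setNames(partition$table$r1, partition$table$gene_id)
  pairs <- enumerate_pairs(partition)
  keep_i <- character(0); keep_j <- character(0); keep_r2 <- numeric(0)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$i[p]; j <- pairs$j[p]
    r2 <- pair_r2(i, j, codes, y, cache)
    if (r2 <= r1[[i]]) next
    r3 <- symmetrical_uncertainty(codes[, i], codes[, j])
    pos <- if (rule == "chain")
      r2 > r1[[j]] && min(r1[[i]], r1[[j]]) > r3
    else
      r1[[j]] > r3
    if (pos) {
      keep_i <- c(keep_i, i); keep_j <- c(keep_j, j); keep_r2 <- c(keep_r2, r2)
      if (length(keep_r2) >= L) break
    }
  }
  if (!length(keep_r2))
    stop("no positive joint feature-pairs found; ",
         "the pair-based forward phase cannot proceed on this data")
  if (length(keep_r2) < L)
    message("only ", length(keep_r2), " positive joint feature-pairs found; ",
            "using all of them")
  structure(list(value = mean(keep_r2), pairs_used = length(keep_r2),
                 pairs = data.frame(i = keep_i, j = keep_j, r2 = keep_r2,
                                    stringsAsFactors = FALSE),
                 rule = rule),
            class = "irda_epsilon")
}

#' @export
print.irda_epsilon <- function(x, ...) {
  cat(sprintf("epsilon = %.6f from %d positive joint feature-pair(s)\n",
              x$value, x$pairs_used))
  invisible(x)
}

#' Forward phase: build seed feature sets from strongly relevant pairs
#'
#' Walks the canonical pair enumeration and keeps every pair whose joint
#' symmetrical uncertainty with the class strictly exceeds `epsilon`. Under
#' `"greedy"` selection the pair is recorded only in the set led by the
#' seed \eqn{f_i}; under `"non_greedy"` and `"semi_greedy"` it is recorded
#' in both sets \eqn{M_i} and \eqn{M_j}. `"semi_greedy"` additionally
#' removes fragmented two-element sets whose seed has strictly lower
#' relevance than its single member. Members of every returned set are
#' ordered by decreasing relevance (gene id breaking ties), seed first.
#'
#' @inheritParams estimate_epsilon
#' @param epsilon numeric threshold, usually `estimate_epsilon(...)$value`.
#' @param mode `"greedy"`, `"semi_greedy"` or `"non_greedy"`.
#' @return named list of character vectors (seed first), ordered by seed
#'   relevance descending; empty list (with a warning) when no pair
#'   qualifies.
#' @export
forward_phase <- function(partition, codes, y, epsilon,
                          mode = c("semi_greedy", "greedy", "non_greedy"),
                          cache = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(epsilon) || length(epsilon) != 1L)
    stop("'epsilon' must be a single number")
  r1 <- stats::setNames(partition$table$r1, partition$table$gene_id)
  pairs <- enumerate_pairs(partition)
  sets <- list()
  add_member <- function(s, f) {
    if (is.null(sets[[s]])) sets[[s]] <<- character(0)
    if (!f %in% sets[[s]]) sets[[s]] <<- c(sets[[s]], f)
  }
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$i[p]; j <- pairs$j[p]
    r2 <- pair_r2(i, j, codes, y, cache)
    if (r2 > epsilon) {
      add_member(i, j)
      if (mode != "greedy") add_member(j, i)
    }
  }
  if (!length(sets)) {
    warning("no feature-pair exceeded epsilon; empty seed collection")
    return(list())
  }
  sets <- lapply(names(sets), function(s) {
    mem <- sets[[s]]
    mem <- mem[order(-r1[mem], mem)]
    c(s, mem)
  })
  names(sets) <- vapply(sets, `[`, "", 1L)
  if (mode == "semi_greedy") {
    frag <- vapply(sets, function(m)
      length(m) == 2L && r1[[m[1L]]] < r1[[m[2L]]], NA)
    sets <- sets[!frag]
    if (!length(sets)) {
      warning("all seed sets were fragments; empty seed collection")
      return(list())
    }
  }
  seeds <- names(sets)
  sets[order(-r1[seeds], seeds)]
}
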