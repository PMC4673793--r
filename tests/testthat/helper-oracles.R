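## Independent brute-force oracles used to cross-check the package's
## information measures, partition clustering and stability formulas.
## These deliberately take different computational routes than the
## implementation (stratified decompositions instead of compound-state
## joint entropies; exhaustive split enumeration instead of dynamic
## programming).

oracle_entropy <- function(x) {
  p <- as.vector(table(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

## H(X|Y) by explicit stratification over the values of y
oracle_cond_entropy <- function(x, y) {
  h <- 0
  for (v in unique(y)) {
    sel <- y == v
    h <- h + mean(sel) * oracle_entropy(x[sel])
  }
  h
}

oracle_joint_entropy <- function(x, y) {
  oracle_entropy(y) + oracle_cond_entropy(x, y)
}

oracle_mi <- function(x, y) oracle_entropy(x) - oracle_cond_entropy(x, y)

## CMI(X, Y | Z) as the stratum-weighted mutual information
oracle_cmi <- function(x, y, z) {
  zc <- if (is.matrix(z) || is.data.frame(z))
    apply(as.matrix(z), 1L, paste, collapse = "|")
  else if (is.list(z)) do.call(paste, z)
  else z
  h <- 0
  for (v in unique(zc)) {
    sel <- zc == v
    h <- h + mean(sel) * oracle_mi(x[sel], y[sel])
  }
  h
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x)
  hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  2 * oracle_mi(x, y) / (hx + hy)
}

oracle_joint_su <- function(x1, x2, y) oracle_su(paste(x1, x2), y)

## Exhaustive optimal 1-D k-means over contiguous splits of a sorted
## vector: enumerates every placement of K-1 cut points and returns the
## minimal within-cluster sum of squares.
oracle_kmeans_1d_sse <- function(v_sorted, K) {
  m <- length(v_sorted)
  S <- c(0, cumsum(v_sorted))
  S2 <- c(0, cumsum(v_sorted^2))
  segc <- function(i, j)               # SSE of v[i..j]
    S2[j + 1] - S2[i] - (S[j + 1] - S[i])^2 / (j - i + 1)
  C <- matrix(0, m, m)
  for (i in 1:m) for (j in i:m) C[i, j] <- segc(i, j)
  if (K == 1) return(C[1, m])
  cuts <- utils::combn(m - 1L, K - 1L)            # (K-1) x NC
  starts <- rbind(1L, cuts + 1L)                  # K x NC
  ends <- rbind(cuts, m)
  tot <- colSums(matrix(C[starts + (ends - 1L) * m], nrow = K))
  min(tot)
}

## Achieved within-cluster SSE of a partition object
partition_sse <- function(p) {
  r1 <- stats::setNames(p$table$r1, p$table$gene_id)
  sum(vapply(p$groups, function(g) sum((r1[g] - mean(r1[g]))^2), 0))
}

## Relative weighted consistency recomputed from an explicit
## occurrence matrix (spreadsheet-style arithmetic)
oracle_rwc <- function(lists, Fsz) {
  genes <- unique(unlist(lists))
  occ <- vapply(lists, function(g) as.integer(genes %in% g),
                integer(length(genes)))
  occ <- matrix(occ, nrow = length(genes))
  N <- sum(occ)
  Rf <- rowSums(occ)
  l <- length(lists)
  Q <- N %% Fsz
  q <- N %% l
  (Fsz * (N - Q + sum(Rf * (Rf - 1))) - N^2 + Q^2) /
    (Fsz * (q^2 + l * (N - q) - Q) - N^2 + Q^2)
}

oracle_overall_jaccard <- function(lists) {
  pairs <- utils::combn(length(lists), 2)
  mean(apply(pairs, 2L, function(ij) {
    a <- unique(lists[[ij[1]]]); b <- unique(lists[[ij[2]]])
    if (!length(union(a, b))) 1 else length(intersect(a, b)) / length(union(a, b))
  }))
}

## random discrete vector helper for property tests
rand_discrete <- function(n, arity) sample(seq_len(arity), n, replace = TRUE)

## A small hand-designed discrete fixture: 6 genes, 12 samples (6 per
## class). Genes a and b misread disjoint class-0 samples as 5 (one for
## a, two for b), so each alone is moderately relevant while the pair
## (a, b) is jointly perfect (class 1 iff both read 5): a complementary
## pair. c and d are weakly relevant, e and f exactly irrelevant.
six_gene_codes <- function() {
  y <- rep(c(0L, 1L), each = 6)
  flip0 <- function(pos) { v <- rep(1L, 6); v[pos] <- 5L; c(v, rep(5L, 6)) }
  codes <- cbind(
    a = flip0(1),
    b = flip0(2:3),
    c = c(1L, 1L, 5L, 1L, 1L, 5L, 5L, 5L, 1L, 5L, 5L, 1L),
    d = c(5L, 1L, 1L, 1L, 5L, 1L, 1L, 5L, 5L, 5L, 1L, 5L),
    e = rep(c(1L, 5L), 6),
    f = rep(c(5L, 1L), 6))
  rownames(codes) <- sprintf("s%02d", 1:12)
  list(codes = codes, y = y)
}

## A hand-assembled relevance partition (valid: contiguous in rank order,
## strictly decreasing group means) used to unit-test the forward phase
## with a chosen Omega_1.
manual_partition <- function(codes, y, groups) {
  tab <- relevance_table(codes, y)
  r1 <- stats::setNames(tab$r1, tab$gene_id)
  means <- vapply(groups, function(g) mean(r1[g]), 0)
  names(groups) <- names(means) <- paste0("Omega", seq_along(groups))
  structure(list(groups = groups, group_means = unname(means),
                 K = length(groups), table = tab),
            class = "irda_partition")
}
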