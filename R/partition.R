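## Relevance ranking and the relevance-based K-partition.

#' Per-gene relevance table
#'
#' Computes the class relevance of every gene as the symmetrical uncertainty
#' between its discretized profile and the class vector, and sorts the
#' result by decreasing relevance (ties broken by gene identifier,
#' ascending), so every downstream stage sees a total, reproducible order.
#'
#' @param codes integer matrix of discretized expression (samples x genes)
#'   as returned by [discretize()]; must have column names.
#' @param y binary class vector, one label per row of `codes`.
#' @return data frame with columns `gene_id` and `r1` (relevance in
#'   \eqn{[0,1]}), sorted by `r1` descending.
#' @export
relevance_table <- function(codes, y) {
  if (is.null(colnames(codes))) stop("'codes' must have column names")
  if (nrow(codes) != length(y)) stop("labels do not match rows of 'codes'")
  r1 <- vapply(seq_len(ncol(codes)),
               function(j) symmetrical_uncertainty(codes[, j], y), 0)
  tab <- data.frame(gene_id = colnames(codes), r1 = r1,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r1, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## Exact 1-D k-means by dynamic programming over contiguous segments of the
## sorted (descending) value list. Works on distinct values with
## multiplicity weights so tied values always share a cluster. Returns the
## optimal segment boundaries (in distinct-value index space).
kmeans_1d_dp <- function(values, weights, K) {
  m <- length(values)
  ## cost(i, j): weighted SSE of distinct values i..j
  cw <- cumsum(weights)
  cwx <- cumsum(weights * values)
  cwx2 <- cumsum(weights * values^2)
  seg_cost <- function(i, j) {
    w <- cw[j] - if (i > 1) cw[i - 1] else 0
    s <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    s2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    s2 - s^2 / w
  }
  D <- matrix(Inf, K, m)       # D[k, j] = min SSE of 1..j using k clusters
  B <- matrix(0L, K, m)        # backpointer: start of last cluster
  for (j in 1:m) {
    D[1, j] <- seg_cost(1, j)
    B[1, j] <- 1L
  }
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:m) {
        best <- Inf; arg <- k
        for (i in k:j) {
          c <- D[k - 1, i - 1] + seg_cost(i, j)
          if (c < best) { best <- c; arg <- i }
        }
        D[k, j] <- best
        B[k, j] <- as.integer(arg)
      }
    }
  }
  bounds <- integer(K)
  j <- m
  for (k in K:1) {
    bounds[k] <- B[k, j]
    j <- bounds[k] - 1L
  }
  list(starts = bounds, sse = D[K, m])
}

#' Relevance-based K-partition of the gene space
#'
#' Splits the relevance-sorted genes into `K` groups by exact
#' one-dimensional k-means on the relevance values, solved by dynamic
#' programming over contiguous segments of the sorted list (optimal 1-D
#' k-means clusters are contiguous in sorted order). The procedure is
#' deterministic and needs no initialization. Groups are labelled
#' \eqn{\Omega_1 \dots \Omega_K} by decreasing group mean; tied relevance
#' values always share a group, so if there are fewer distinct values than
#' `K` the effective number of groups shrinks (with a warning).
#'
#' @param table relevance table from [relevance_table()].
#' @param K requested number of groups (default 5).
#' @return object of class `"irda_partition"`: list with `groups` (list of
#'   gene-id vectors, each internally ordered by decreasing relevance),
#'   `group_means`, `K` (effective), and the input `table`.
#' @export
build_partition <- function(table, K = 5) {
  if (K < 2) stop("'K' must be at least 2")
  if (nrow(table) < K)
    stop("fewer genes (", nrow(table), ") than groups requested (", K, ")")
  vals <- table$r1                       # already sorted descending
  distinct <- unique(vals)               # descending
  Keff <- as.integer(min(K, length(distinct)))
  if (Keff < K)
    warning("only ", length(distinct), " distinct relevance values; ",
            "effective K reduced to ", Keff)
  fit <- kmeans_1d_dp(distinct, as.numeric(tabulate(match(vals, distinct))), Keff)
  ## map distinct-value segments back to gene rows
  seg_of_distinct <- rep(seq_len(Keff),
                         times = diff(c(fit$starts, length(distinct) + 1L)))
  seg <- seg_of_distinct[match(vals, distinct)]
  groups <- split(table$gene_id, seg)
  means <- vapply(split(vals, seg), mean, 0)
  names(groups) <- names(means) <- paste0("Omega", seq_len(Keff))
  structure(list(groups = groups, group_means = unname(means),
                 K = Keff, table = table, sse = fit$sse),
            class = "irda_partition")
}

#' @export
print.irda_partition <- function(x, ...) {
  cat("Relevance-based K-partition (K =", x$K, ")\n")
  for (k in seq_len(x$K))
    cat(sprintf("  Omega%-2d %5d genes, mean relevance %.4f\n",
                k, length(x$groups[[k]]), x$group_means[k]))
  invisible(x)
}
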