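#' Fit the iRDA candidate-gene filter
#'
#' Runs the full four-step pipeline on a continuous expression matrix with
#' binary class labels: (1) discretize each gene around its mean and rank
#' all genes by symmetrical uncertainty with the class; (2) partition the
#' ranked genes into `K` relevance groups by exact 1-D k-means; (3) scan
#' feature-pairs led by top-group seeds, keep pairs whose joint symmetrical
#' uncertainty exceeds the estimated threshold \eqn{\varepsilon}, and prune
#' each resulting seed set by conditional-mutual-information backward
#' elimination (greedy mode interleaves an insertion phase between two
#' backward runs); (4) aggregate the surviving parsimony models, ranked by
#' seed relevance, into a de-duplicated candidate gene set.
#'
#' The whole procedure is deterministic: all ties are broken by gene
#' identifier, and the 1-D clustering is solved exactly, so repeated runs
#' on the same input give identical output.
#'
#' @param x numeric matrix of expression values, samples in rows, genes in
#'   columns (column names required), or an object with `$x` and `$y`
#'   components such as the datasets produced by [simulate_expression()].
#' @param y binary class vector (two distinct values; coerced to 0/1 with
#'   the lexicographically smaller original label mapped to 0). Ignored
#'   when `x` carries its own labels.
#' @param mode selection mode: `"semi_greedy"` (default), `"greedy"` or
#'   `"non_greedy"`.
#' @param K number of relevance groups (default 5).
#' @param L number of positive joint feature-pairs averaged into
#'   \eqn{\varepsilon} (default 100).
#' @param epsilon optional numeric override of the estimated threshold.
#' @param tol conditional-mutual-information zero tolerance for the
#'   redundancy test (default `1e-12`).
#' @param sd_type standard deviation flavour for discretization.
#' @param epsilon_rule positive-pair criterion, `"chain"` or `"literal"`
#'   (see [estimate_epsilon()]).
#' @param knn_k neighbourhood size stored for downstream evaluation
#'   (default 3; must be odd).
#' @param keep_data keep the input matrix inside the fit (default `TRUE`;
#'   needed by [predict.irda()] and [ma_knn_wrapper()]).
#' @return an object of class `"irda"`; see Details.
#' @details The returned object is a list with components `candidates`
#'   (data frame: `rank`, `gene_id`, `seed_set_index`, `r1`), `models`
#'   (the parsimony models, G_post), `g_pre` (seed sets before backward
#'   elimination), `epsilon`, `partition`, `relevance`, `config`, and the
#'   training data (`x`, `y`) when `keep_data = TRUE`.
#' @seealso [ma_knn_wrapper()], [loo_stability()], [simulate_expression()]
#' @examples
#' sim <- simulate_expression(planted_design(n_samples = 40, n_genes = 80), seed = 1)
#' fit <- irda(sim$dataset)
#' fit
#' @export
irda <- function(x, y = NULL, mode = c("semi_greedy", "greedy", "non_greedy"),
                 K = 5, L = 100, epsilon = NULL, tol = 1e-12,
                 sd_type = c("sample", "population"),
                 epsilon_rule = c("chain", "literal"),
                 knn_k = 3, keep_data = TRUE) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  epsilon_rule <- match.arg(epsilon_rule)
  cl <- match.call()
  if (is.list(x) && !is.null(x$x)) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("'x' must have gene identifiers as column names")
  if (anyDuplicated(colnames(x)))
    stop("duplicated gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (is.null(y)) stop("class labels 'y' are required")
  y <- encode_labels(y)
  if (length(y) != nrow(x)) stop("length of 'y' must equal nrow(x)")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 samples and 2 genes")
  if (knn_k %% 2 == 0) stop("'knn_k' must be odd (binary majority vote)")

  codes <- discretize(x, sd_type = sd_type)
  relevance <- relevance_table(codes, y)
  partition <- build_partition(relevance, K = K)
  r1 <- stats::setNames(relevance$r1, relevance$gene_id)

  cache <- new.env(parent = emptyenv())
  eps <- if (is.null(epsilon)) {
    estimate_epsilon(partition, codes, y, L = L, rule = epsilon_rule,
                     cache = cache)
  } else {
    structure(list(value = epsilon, pairs_used = NA_integer_,
                   pairs = NULL, rule = "override"),
              class = "irda_epsilon")
  }

  g_pre <- forward_phase(partition, codes, y, eps$value, mode = mode,
                         cache = cache)
  if (mode == "greedy") {
    g_mid <- backward_phase(g_pre, codes, y, tol)
    g_mid <- insertion_phase(g_mid, r1)
    models <- backward_phase(g_mid, codes, y, tol)
  } else {
    models <- backward_phase(g_pre, codes, y, tol)
  }
  if (length(models)) {
    seeds <- names(models)
    models <- models[order(-r1[seeds], seeds)]
  }
  candidates <- suppressWarnings(aggregate_candidates(models, r1))
  if (!nrow(candidates))
    warning("no parsimony model survived; empty candidate set")

  structure(list(candidates = candidates, models = models, g_pre = g_pre,
                 epsilon = eps, partition = partition, relevance = relevance,
                 config = list(mode = mode, K = K, L = L, tol = tol,
                               sd_type = sd_type, epsilon_rule = epsilon_rule,
                               knn_k = knn_k),
                 x = if (keep_data) x else NULL,
                 y = if (keep_data) y else NULL,
                 call = cl),
            class = "irda")
}

## Map a two-level label vector to integer 0/1; the lexicographically
## smaller original label becomes 0. Already-0/1 input passes through.
encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L)
    stop("expected exactly 2 distinct class labels, found ", length(lev),
         ": ", paste(utils::head(lev, 5L), collapse = ", "))
  out <- as.integer(as.character(y) == lev[2L])
  attr(out, "levels") <- lev
  out
}

#' @export
print.irda <- function(x, ...) {
  cat("iRDA candidate-gene filter (mode:", x$config$mode, ")\n")
  cat(sprintf("  %d genes, %d samples; epsilon = %.4f (%s)\n",
              nrow(x$relevance), length(x$y %||% numeric(0)),
              x$epsilon$value,
              if (is.na(x$epsilon$pairs_used)) "fixed override"
              else paste(x$epsilon$pairs_used, "positive pairs")))
  cat(sprintf("  %d seed set(s) -> %d parsimony model(s) -> %d candidate gene(s)\n",
              length(x$g_pre), length(x$models), nrow(x$candidates)))
  if (nrow(x$candidates))
    cat("  candidates:", paste(utils::head(x$candidates$gene_id, 10L),
                               collapse = ", "),
        if (nrow(x$candidates) > 10L) "..." else "", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.irda <- function(object, ...) {
  ans <- list(config = object$config, epsilon = object$epsilon,
              partition_sizes = lengths(object$partition$groups),
              models = object$models, candidates = object$candidates)
  class(ans) <- "summary.irda"
  ans
}

#' @export
print.summary.irda <- function(x, ...) {
  cat("iRDA fit (mode:", x$config$mode, ")\n\nPartition sizes:\n")
  print(x$partition_sizes)
  cat("\n")
  print(x$epsilon)
  cat("\nParsimony models:\n")
  if (!length(x$models)) cat("  (none)\n")
  for (s in names(x$models))
    cat("  ", s, ": {", paste(x$models[[s]], collapse = ", "), "}\n", sep = "")
  cat("\nCandidate genes:\n")
  print(x$candidates)
  invisible(x)
}

#' Relevance values of the selected candidate genes
#' @param object an `"irda"` fit.
#' @param ... unused.
#' @return named numeric vector of symmetrical-uncertainty relevance
#'   values, in candidate rank order.
#' @export
coef.irda <- function(object, ...) {
  stats::setNames(object$candidates$r1, object$candidates$gene_id)
}

#' Classify new samples with a k-nearest-neighbour vote on the candidates
#'
#' Nearest neighbours are found among the training samples by Euclidean
#' distance on the candidate genes, z-scored with training means and
#' standard deviations.
#'
#' @param object an `"irda"` fit created with `keep_data = TRUE`.
#' @param newdata numeric matrix (samples x genes) containing at least the
#'   candidate genes; defaults to the training matrix.
#' @param k neighbourhood size; defaults to the stored `knn_k`.
#' @param type `"class"` for 0/1 labels, `"score"` for the positive-class
#'   neighbour fraction.
#' @param ... unused.
#' @export
predict.irda <- function(object, newdata = NULL, k = NULL,
                         type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$x)) stop("fit was created with keep_data = FALSE")
  if (!nrow(object$candidates)) stop("empty candidate set; nothing to predict with")
  k <- k %||% object$config$knn_k
  genes <- object$candidates$gene_id
  if (is.null(newdata)) newdata <- object$x
  newdata <- as.matrix(newdata)
  missing <- setdiff(genes, colnames(newdata))
  if (length(missing))
    stop("newdata lacks candidate gene(s): ", paste(missing, collapse = ", "))
  tr <- object$x[, genes, drop = FALSE]
  mu <- colMeans(tr)
  sg <- apply(tr, 2L, stats::sd)
  sg[sg == 0] <- 1
  trz <- scale(tr, center = mu, scale = sg)
  tez <- scale(newdata[, genes, drop = FALSE], center = mu, scale = sg)
  score <- apply(tez, 1L, function(v) {
    d <- sqrt(colSums((t(trz) - v)^2))
    nb <- order(d)[seq_len(min(k, length(d)))]
    mean(object$y[nb] == 1L)
  })
  if (type == "score") score else as.integer(score > 0.5)
}

#' Plot an iRDA fit
#'
#' Shows the sorted per-gene relevance values with the K-partition group
#' boundaries, highlighting the selected candidate genes.
#'
#' @param x an `"irda"` fit.
#' @param ... passed to [plot()].
#' @export
plot.irda <- function(x, ...) {
  tab <- x$relevance
  grp <- rep(seq_along(x$partition$groups), lengths(x$partition$groups))
  plot(seq_len(nrow(tab)), tab$r1, col = grp, pch = 16, cex = 0.6,
       xlab = "relevance rank", ylab = "SU(gene, class)",
       main = "Relevance partition", ...)
  sel <- match(x$candidates$gene_id, tab$gene_id)
  if (length(sel)) points(sel, tab$r1[sel], pch = 1, cex = 1.4)
  cuts <- cumsum(lengths(x$partition$groups))
  abline(v = utils::head(cuts, -1) + 0.5, lty = 3, col = "grey40")
  invisible(x)
}
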