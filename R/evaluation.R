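## LOOCV k-nearest-neighbour evaluation and the MA-kNN wrapper.

#' Leave-one-out kNN classification on a gene subset
#'
#' For every sample, its `k` nearest neighbours among the remaining
#' samples are found by Euclidean distance on the selected genes, z-scored
#' with means and standard deviations computed on the training fold only
#' (no leakage). The predicted label is the neighbour majority and the
#' score is the fraction of neighbours in the positive class. Distance ties
#' are broken by sample index.
#'
#' @param x numeric expression matrix (samples x genes).
#' @param y binary class vector (0/1 or two labels; see [irda()]).
#' @param genes character vector of gene ids to use (at least one).
#' @param k neighbourhood size, `k < n` (default 3; odd avoids vote ties).
#' @param space `"continuous"` (default) evaluates distances on z-scored
#'   continuous values; `"discretized"` on the 1/3/5 codes.
#' @param positive which encoded class (0 or 1) counts as positive for the
#'   confusion table and scores (default 1).
#' @return object of class `"irda_loocv"`: list with `predicted`, `score`,
#'   `y`, and confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
loocv_knn <- function(x, y, genes, k = 3,
                      space = c("continuous", "discretized"), positive = 1L) {
  space <- match.arg(space)
  x <- as.matrix(x)
  y <- encode_labels(y)
  if (length(y) != nrow(x)) stop("labels do not match rows of 'x'")
  if (!length(genes)) stop("need at least one gene")
  missing <- setdiff(genes, colnames(x))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  n <- nrow(x)
  if (k >= n) stop("'k' must be smaller than the number of samples")
  sub <- x[, genes, drop = FALSE]
  if (space == "discretized") sub <- discretize(sub)
  pred <- integer(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    tr <- sub[-i, , drop = FALSE]
    if (space == "continuous") {
      mu <- colMeans(tr)
      sg <- apply(tr, 2L, stats::sd)
      sg[sg == 0] <- 1
      trz <- scale(tr, center = mu, scale = sg)
      te <- (sub[i, ] - mu) / sg
    } else {
      trz <- tr
      te <- sub[i, ]
    }
    d <- sqrt(rowSums((trz - rep(te, each = n - 1L))^2))
    nb <- order(d)[seq_len(k)]          # order() breaks ties by index
    ytr <- y[-i][nb]
    score[i] <- mean(ytr == positive)
    pred[i] <- if (mean(ytr == 1L) > 0.5) 1L else 0L
  }
  pos <- y == positive
  predpos <- if (positive == 1L) pred == 1L else pred == 0L
  structure(list(predicted = pred, score = score, y = y, positive = positive,
                 tp = sum(pos & predpos), tn = sum(!pos & !predpos),
                 fp = sum(!pos & predpos), fn = sum(pos & !predpos)),
            class = "irda_loocv")
}

#' @export
print.irda_loocv <- function(x, ...) {
  cat(sprintf("LOOCV-kNN outcome: TP %d  TN %d  FP %d  FN %d | Error %.2f%%  AUC %.4f  MCC %.4f\n",
              x$tp, x$tn, x$fp, x$fn, error_rate(x), auc(x), mcc(x)))
  invisible(x)
}

#' Generalization error of a LOOCV outcome, in percent
#' @param outcome an `"irda_loocv"` object.
#' @return `(FP + FN) / n * 100`.
#' @export
error_rate <- function(outcome) {
  n <- outcome$tp + outcome$tn + outcome$fp + outcome$fn
  100 * (outcome$fp + outcome$fn) / n
}

#' Matthews correlation coefficient of a LOOCV outcome
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0
#' when any factor of the denominator vanishes.
#' @inheritParams error_rate
#' @export
mcc <- function(outcome) {
  tp <- outcome$tp; tn <- outcome$tn; fp <- outcome$fp; fn <- outcome$fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve of a LOOCV outcome
#'
#' Mann-Whitney statistic of the positive-class scores: the fraction of
#' (positive, negative) sample pairs where the positive sample scores
#' higher, ties counted one half. A constant score vector gives exactly 0.5.
#' @inheritParams error_rate
#' @export
auc <- function(outcome) {
  pos <- outcome$y == outcome$positive
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(outcome$score, ties.method = "average")
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' MA-kNN wrapper: sequential forward evaluation of a candidate gene set
#'
#' Starting from an initial examined set `initial` (for iRDA fits the first
#' parsimony model; for one-by-one filters the first gene), the wrapper
#' repeatedly evaluates every remaining candidate joined to the examined
#' set under LOOCV-kNN and admits the *successive victory gene*: the unique
#' MCC maximizer, or — when the maximal MCC is tied — the AUC maximizer
#' among the tied genes (any residual tie broken by gene id, ascending,
#' with a message). One evaluation point (examined set, Error, AUC, MCC) is
#' appended per step until the candidate list is exhausted.
#'
#' @param object an `"irda"` fit (with data kept), or a character vector of
#'   candidate gene ids if `x` and `y` are supplied.
#' @param x,y expression matrix and labels (taken from the fit if omitted).
#' @param initial initial examined gene set; defaults to the first
#'   parsimony model for an `"irda"` fit and to the first gene otherwise.
#' @param k neighbourhood size (default: fit's `knn_k`, else 3).
#' @param space distance space passed to [loocv_knn()].
#' @return object of class `"irda_profile"`: data frame with one row per
#'   evaluation point and columns `step`, `gene` (gene admitted at this
#'   step, `NA` for the initial point), `n_genes`, `error_pct`, `auc`,
#'   `mcc`, plus attribute `genes` (the examined set order).
#' @export
ma_knn_wrapper <- function(object, x = NULL, y = NULL, initial = NULL,
                           k = NULL, space = "continuous") {
  if (inherits(object, "irda")) {
    genes <- object$candidates$gene_id
    x <- x %||% object$x
    y <- y %||% object$y
    k <- k %||% object$config$knn_k
    if (is.null(initial) && length(object$models))
      initial <- object$models[[1L]]
  } else {
    genes <- as.character(object)
  }
  if (is.null(x) || is.null(y)) stop("'x' and 'y' are required")
  k <- k %||% 3
  if (!length(genes)) stop("empty candidate gene set")
  if (is.null(initial)) initial <- genes[1L]
  initial <- intersect(genes, initial)  # keep candidate order, drop strays
  if (!length(initial)) initial <- genes[1L]
  remaining <- setdiff(genes, initial)

  eval_point <- function(set, gene, step) {
    out <- loocv_knn(x, y, set, k = k, space = space)
    data.frame(step = step, gene = gene, n_genes = length(set),
               error_pct = error_rate(out), auc = auc(out), mcc = mcc(out),
               stringsAsFactors = FALSE)
  }
  O <- initial
  profile <- eval_point(O, NA_character_, 0L)
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    stats <- vapply(remaining, function(f) {
      out <- loocv_knn(x, y, c(O, f), k = k, space = space)
      c(mcc = mcc(out), auc = auc(out))
    }, c(mcc = 0, auc = 0))
    m <- stats["mcc", ]
    tied <- remaining[abs(m - max(m)) < 1e-12]
    if (length(tied) > 1L) {
      a <- stats["auc", match(tied, remaining)]
      tied <- tied[abs(a - max(a)) < 1e-12]
      if (length(tied) > 1L) {
        message("AUC tie broken by gene id: ", paste(sort(tied), collapse = ", "))
        tied <- sort(tied)
      }
    }
    g <- tied[1L]
    O <- c(O, g)
    remaining <- setdiff(remaining, g)
    profile <- rbind(profile, eval_point(O, g, step))
  }
  rownames(profile) <- NULL
  attr(profile, "genes") <- O
  class(profile) <- c("irda_profile", "data.frame")
  profile
}

#' @export
print.irda_profile <- function(x, ...) {
  cat("MA-kNN evaluation profile (", nrow(x), " points)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot an MA-kNN evaluation profile
#' @param x an `"irda_profile"`.
#' @param ... passed to [matplot()].
#' @export
plot.irda_profile <- function(x, ...) {
  graphics::matplot(x$n_genes, cbind(x$error_pct / 100, x$auc, x$mcc),
                    type = "b", pch = 16, lty = 1,
                    xlab = "genes examined", ylab = "measure",
                    col = c("firebrick", "steelblue", "darkgreen"), ...)
  graphics::legend("bottomright", c("Error (fraction)", "AUC", "MCC"),
                   col = c("firebrick", "steelblue", "darkgreen"),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
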