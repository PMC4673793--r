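## Plug-in information measures on discrete vectors, log base 2 throughout.
## All probabilities are maximum-likelihood (count / n) with no pseudocounts:
## the redundancy criterion relies on exact zeros when empirical counts
## factorize, which pseudocounts would destroy.

#' Three-level discretization of an expression matrix
#'
#' Codes each gene independently around its mean: values below
#' \eqn{\mu - \sigma/2} become 1, values in the closed interval
#' \eqn{[\mu - \sigma/2, \mu + \sigma/2]} become 3, and values above
#' \eqn{\mu + \sigma/2} become 5. Both interval endpoints map to 3.
#'
#' @param x numeric matrix, samples in rows and genes in columns.
#' @param sd_type `"sample"` (default, `n - 1` denominator) or
#'   `"population"` (`n` denominator) standard deviation.
#' @return integer matrix of the same shape and dimnames with entries in
#'   `{1, 3, 5}`. Constant genes (zero standard deviation) are coded 3
#'   everywhere and reported in a single warning.
#' @export
discretize <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  if (anyNA(x)) stop("'x' contains missing values; impute or filter first")
  n <- nrow(x)
  mu <- colMeans(x)
  sg <- apply(x, 2L, stats::sd)
  if (sd_type == "population") sg <- sg * sqrt((n - 1) / n)
  const <- !is.na(sg) & sg == 0
  codes <- matrix(3L, n, ncol(x), dimnames = dimnames(x))
  lo <- rep(mu - sg / 2, each = n)
  hi <- rep(mu + sg / 2, each = n)
  codes[x < lo] <- 1L
  codes[x > hi] <- 5L
  if (any(const)) {
    codes[, const] <- 3L
    warning(sum(const), " constant gene(s) coded 3 throughout: ",
            paste(utils::head(colnames(x)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
  }
  codes
}

## Collapse one or more discrete vectors / matrix columns into a single
## integer code vector whose values index the observed joint states.
compound_states <- function(...) {
  parts <- list(...)
  cols <- list()
  for (p in parts) {
    if (is.null(p)) next
    if (is.matrix(p) || is.data.frame(p)) {
      for (j in seq_len(ncol(p))) cols[[length(cols) + 1L]] <- p[, j]
    } else if (is.list(p)) {
      for (q in p) cols[[length(cols) + 1L]] <- q
    } else {
      cols[[length(cols) + 1L]] <- p
    }
  }
  if (!length(cols)) stop("no vectors supplied")
  n <- length(cols[[1L]])
  if (any(vapply(cols, length, 1L) != n)) stop("length mismatch among vectors")
  if (length(cols) == 1L) {
    key <- cols[[1L]]
  } else {
    key <- do.call(paste, c(cols, sep = "\r"))
  }
  match(key, unique(key))
}

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Shannon entropy of a discrete vector (bits)
#'
#' Plug-in estimate \eqn{H(X) = -\sum_x p(x) \log_2 p(x)} with
#' \eqn{p(x)} the empirical frequency and \eqn{0 \log 0 := 0}.
#'
#' @param x vector of discrete states (any atomic type).
#' @return non-negative entropy in bits.
#' @export
entropy <- function(x) {
  if (length(x) == 0L) stop("empty vector")
  entropy_from_counts(tabulate(compound_states(x)))
}

#' Joint entropy of two discrete vectors (bits)
#' @param x,y equal-length vectors of discrete states.
#' @return \eqn{H(X, Y)} in bits.
#' @export
joint_entropy <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  entropy(compound_states(x, y))
}

#' Conditional entropy H(X | Y) (bits)
#'
#' Computed as \eqn{H(X, Y) - H(Y)}; always in \eqn{[0, H(X)]} up to
#' floating-point noise.
#' @inheritParams joint_entropy
#' @export
conditional_entropy <- function(x, y) {
  max(joint_entropy(x, y) - entropy(y), 0)
}

#' Mutual information MI(X, Y) (bits)
#'
#' \eqn{MI(X,Y) = H(X) - H(X|Y)}; symmetric and non-negative.
#' @inheritParams joint_entropy
#' @export
mutual_information <- function(x, y) {
  max(entropy(x) + entropy(y) - joint_entropy(x, y), 0)
}

#' Conditional mutual information CMI(X, Y | Z) (bits)
#'
#' \eqn{CMI(X,Y|Z) = H(X|Z) - H(X|Y,Z)}. The conditioning set `z` is
#' compounded into one variable whose states are the observed tuples of
#' member states; unobserved tuples contribute nothing to the plug-in sums.
#' The estimate is exactly zero iff the empirical counts factorize within
#' every stratum of `z`.
#'
#' @inheritParams joint_entropy
#' @param z a vector, matrix (columns are variables), or list of vectors
#'   forming the conditioning set; `NULL` or empty degrades to
#'   [mutual_information()].
#' @export
conditional_mutual_information <- function(x, y, z = NULL) {
  if (length(x) != length(y)) stop("length mismatch")
  if (is.null(z) || (is.list(z) && !length(z))) return(mutual_information(x, y))
  zc <- compound_states(z)
  if (length(zc) != length(x)) stop("length mismatch")
  ## H(X|Z) - H(X|Y,Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)
  h <- entropy(compound_states(x, zc)) + entropy(compound_states(y, zc)) -
    entropy(zc) - entropy(compound_states(x, y, zc))
  max(h, 0)
}

#' Symmetrical uncertainty SU(X, Y)
#'
#' \eqn{SU = 2 \, MI(X,Y) / (H(X) + H(Y))}, a normalised mutual information
#' in \eqn{[0, 1]}, symmetric and invariant to the log base. When both
#' variables are constant the denominator vanishes and SU is defined as 0
#' (with a warning).
#' @inheritParams joint_entropy
#' @export
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy(x)
  hy <- entropy(y)
  if (hx + hy == 0) {
    warning("both variables constant; SU defined as 0")
    return(0)
  }
  su <- 2 * max(hx + hy - joint_entropy(x, y), 0) / (hx + hy)
  min(max(su, 0), 1)
}

#' Joint symmetrical uncertainty SU(X1, X2; Y)
#'
#' Treats the pair `(x1, x2)` as one compound variable:
#' \deqn{SU_{x_1,x_2;y} = 2 \frac{H(x_1,x_2) - H(x_1,x_2 | y)}{H(x_1,x_2) + H(y)}.}
#' @param x1,x2,y equal-length vectors of discrete states.
#' @export
joint_symmetrical_uncertainty <- function(x1, x2, y) {
  if (length(x1) != length(x2) || length(x1) != length(y))
    stop("length mismatch")
  symmetrical_uncertainty(compound_states(x1, x2), y)
}
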