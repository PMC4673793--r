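## Planted-signal synthetic expression data: the structure the filter
## assumes (m >> n, a handful of informative genes including a pairwise
## synergistic pair and near-duplicate copies, the rest independent
## Gaussian noise, mild class imbalance).

#' Describe a planted-signal simulation design
#'
#' @param n_samples number of samples (default 60).
#' @param n_genes total number of genes (default 500).
#' @param imbalance_ratio majority/minority class ratio, >= 1 (default 1.5).
#' @param n_strong number of individually relevant genes (default 2), each
#'   with a class-conditional mean shift of `effect_size` noise-sd units.
#' @param effect_size mean shift of strong genes in noise-sd units
#'   (default 1.5).
#' @param n_synergy_pairs number of XOR-style gene pairs (default 1):
#'   each arm takes sign +/- `synergy_amp` at random, marginally balanced
#'   and independent of the class, while the product of the two discretized
#'   signs determines the class exactly — individually uninformative,
#'   jointly predictive.
#' @param synergy_amp arm amplitude of synergy genes in noise-sd units
#'   (default 4; large enough that the middle discretization band is
#'   rarely occupied and the joint pattern survives coding).
#' @param n_duplicates number of jittered copies of the first strong gene
#'   (default 3).
#' @param duplicate_jitter standard deviation of the duplicate jitter in
#'   noise-sd units (default 0.05).
#' @return object of class `"planted_design"`.
#' @export
planted_design <- function(n_samples = 60, n_genes = 500,
                           imbalance_ratio = 1.5, n_strong = 2,
                           effect_size = 1.5, n_synergy_pairs = 1,
                           synergy_amp = 4, n_duplicates = 3,
                           duplicate_jitter = 0.05) {
  planted <- n_strong + 2 * n_synergy_pairs + n_duplicates
  if (n_genes < planted)
    stop("design infeasible: ", n_genes, " genes cannot host ", planted,
         " planted genes")
  if (imbalance_ratio < 1) stop("'imbalance_ratio' must be >= 1")
  if (n_strong > 0 && effect_size <= 0) stop("'effect_size' must be positive")
  if (n_duplicates > 0 && n_strong < 1)
    stop("duplicates need at least one strong gene as parent")
  if (n_samples < 4) stop("need at least 4 samples")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 imbalance_ratio = imbalance_ratio, n_strong = n_strong,
                 effect_size = effect_size,
                 n_synergy_pairs = n_synergy_pairs,
                 synergy_amp = synergy_amp, n_duplicates = n_duplicates,
                 duplicate_jitter = duplicate_jitter),
            class = "planted_design")
}

#' Generate a planted-signal expression dataset
#'
#' Produces a samples x genes matrix of continuous values with unit
#' Gaussian noise, a binary class vector matching the design's imbalance
#' ratio, and a ground-truth annotation of every gene's role
#' (`strong`, `synergy`, `duplicate`, `noise`), sufficient to score any
#' selector's recovery precision and recall. Planted genes are placed at
#' seeded-random column positions. Identical seeds give identical datasets.
#'
#' @param design a [planted_design()].
#' @param seed integer random seed.
#' @return list with `dataset` (list: `x` matrix, `y` 0/1 labels,
#'   `gene_ids`, `sample_ids`) and `truth` (data frame: `gene_id`, `role`,
#'   `parent`, `pair`).
#' @export
simulate_expression <- function(design, seed = 1L) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(as.integer(seed))
  n <- design$n_samples
  m <- design$n_genes
  n1 <- round(n * design$imbalance_ratio / (1 + design$imbalance_ratio))
  n1 <- min(max(n1, 1L), n - 1L)
  y <- sample(c(rep(1L, n1), rep(0L, n - n1)))

  gene_ids <- sprintf("g%04d", seq_len(m))
  x <- matrix(stats::rnorm(n * m), n, m,
              dimnames = list(sprintf("s%03d", seq_len(n)), gene_ids))

  n_planted <- design$n_strong + 2 * design$n_synergy_pairs +
    design$n_duplicates
  slots <- sample(m, n_planted)
  role <- rep("noise", m)
  parent <- rep(NA_character_, m)
  pair <- rep(NA_integer_, m)
  p <- 0L
  strong_cols <- integer(0)
  for (s in seq_len(design$n_strong)) {
    p <- p + 1L
    j <- slots[p]
    x[, j] <- x[, j] + design$effect_size * y
    role[j] <- "strong"
    strong_cols <- c(strong_cols, j)
  }
  for (d in seq_len(design$n_duplicates)) {
    p <- p + 1L
    j <- slots[p]
    x[, j] <- x[, strong_cols[1L]] +
      stats::rnorm(n, sd = design$duplicate_jitter)
    role[j] <- "duplicate"
    parent[j] <- gene_ids[strong_cols[1L]]
  }
  for (q in seq_len(design$n_synergy_pairs)) {
    a_sign <- sample(c(-1, 1), n, replace = TRUE)
    b_sign <- a_sign * (2 * y - 1)       # sign product encodes the class
    p <- p + 1L; ja <- slots[p]
    p <- p + 1L; jb <- slots[p]
    x[, ja] <- a_sign * design$synergy_amp + stats::rnorm(n)
    x[, jb] <- b_sign * design$synergy_amp + stats::rnorm(n)
    role[c(ja, jb)] <- "synergy"
    pair[c(ja, jb)] <- q
  }
  truth <- data.frame(gene_id = gene_ids, role = role, parent = parent,
                      pair = pair, stringsAsFactors = FALSE)
  list(dataset = list(x = x, y = y, gene_ids = gene_ids,
                      sample_ids = rownames(x)),
       truth = truth)
}

#' Score a selector's recovery of the planted signal
#'
#' Compares a selected gene list against the ground-truth annotation. A
#' strong gene and its jittered duplicates are statistically
#' interchangeable, so they are scored as one equivalence class: the class
#' counts as recovered when any of its members is selected. Synergy genes
#' are scored individually.
#'
#' @param genes character vector of selected gene ids (or an `"irda"`
#'   fit).
#' @param truth truth data frame from [simulate_expression()].
#' @return list with `strong_recovered` / `strong_total` (equivalence
#'   classes), `synergy_recovered` / `synergy_total` (individual genes),
#'   `n_selected`, and `false_positives` (selected genes annotated as
#'   noise).
#' @export
score_recovery <- function(genes, truth) {
  if (inherits(genes, "irda")) genes <- genes$candidates$gene_id
  strong <- truth$gene_id[truth$role == "strong"]
  classes <- lapply(strong, function(s)
    c(s, truth$gene_id[!is.na(truth$parent) & truth$parent == s]))
  synergy <- truth$gene_id[truth$role == "synergy"]
  noise <- truth$gene_id[truth$role == "noise"]
  list(strong_recovered = sum(vapply(classes, function(cl) any(cl %in% genes), NA)),
       strong_total = length(classes),
       synergy_recovered = sum(synergy %in% genes),
       synergy_total = length(synergy),
       n_selected = length(genes),
       false_positives = sum(genes %in% noise))
}
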