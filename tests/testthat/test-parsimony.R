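## Backward elimination, insertion, aggregation, and the full pipeline.

test_that("redundancy test: exact duplicate true, informative gene false", {
  fx <- six_gene_codes()
  codes <- cbind(fx$codes, a2 = fx$codes[, "a"])   # exact copy of a
  y <- fx$y
  expect_true(is_redundant("a2", c("b", "a", "a2"), codes, y))
  expect_true(is_redundant("a", c("b", "a", "a2"), codes, y))
  ## f carrying the labels themselves, conditioned on pure noise: not redundant
  codes2 <- cbind(lab = ifelse(y == 1, 5L, 1L), e = fx$codes[, "e"])
  expect_false(is_redundant("lab", c("lab", "e"), codes2, y))
  expect_error(is_redundant("lab", "lab", codes2, y), "empty")
  expect_error(is_redundant("zz", c("lab", "e"), codes2, y), "not a member")
})

test_that("crafted 8-sample fixture with factorizing strata is redundant", {
  ## conditioning on z: within each z-stratum, f and y counts factorize
  ## (f independent of y given z), so plug-in CMI is exactly zero
  y <- c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  z <- c(1L, 1L, 1L, 1L, 5L, 5L, 5L, 5L)
  f <- c(1L, 5L, 1L, 5L, 3L, 3L, 3L, 3L)   # balanced vs y inside z = 1
  codes <- cbind(f = f, z = z)
  expect_identical(oracle_cmi(f, y, list(z)), 0)
  expect_true(is_redundant("f", c("z", "f"), codes, y))
})

test_that("first-seat-last-check removes the duplicate, keeps the pair", {
  fx <- six_gene_codes()
  codes <- cbind(fx$codes, a2 = fx$codes[, "a"])
  y <- fx$y
  ## seed a, members ordered by relevance: a, a2 (tied, id tie-break), b
  out <- backward_phase(list(a = c("a", "a2", "b")), codes, y)
  expect_identical(out$a, c("a", "a2", "b")[c(1, 3)])
  ## the complementary member b survives: it completes the seed
  expect_identical(out$a, c("a", "b"))
})

test_that("two-member set with neither member redundant is unchanged", {
  fx <- six_gene_codes()
  out <- backward_phase(list(a = c("a", "b")), fx$codes, fx$y)
  expect_identical(out$a, c("a", "b"))
})

test_that("a set whose seed is redundant given survivors is discarded", {
  y <- rep(c(0L, 1L), each = 6)
  perfect <- ifelse(y == 1, 5L, 1L)
  weak <- perfect; weak[c(1, 7)] <- c(5L, 1L)   # weaker copy of the signal
  codes <- cbind(s = weak, a = perfect)
  ## member a (perfect) checked first: informative beyond s -> kept;
  ## seed s checked last: CMI(s, C | {a}) = 0 since a determines C
  expect_length(backward_phase(list(s = c("s", "a")), codes, y), 0L)
})

test_that("backward elimination is idempotent on pipeline outputs", {
  for (sd in c(3, 4, 6)) {
    sim <- simulate_expression(planted_design(), seed = sd)
    fit <- suppressWarnings(suppressMessages(irda(sim$dataset)))
    codes <- discretize(sim$dataset$x)
    again <- backward_phase(fit$models, codes, sim$dataset$y,
                            tol = fit$config$tol)
    expect_identical(again[order(names(again))],
                     fit$models[order(names(fit$models))])
  }
})

test_that("surviving models have positive conditional information throughout", {
  sim <- simulate_expression(planted_design(), seed = 4)
  fit <- suppressWarnings(suppressMessages(irda(sim$dataset)))
  codes <- discretize(sim$dataset$x)
  for (s in names(fit$models)) {
    m <- fit$models[[s]]
    expect_gte(length(m), 2L)
    for (f in m)
      expect_gt(conditional_mutual_information(
        codes[, f], sim$dataset$y, codes[, setdiff(m, f), drop = FALSE]),
        fit$config$tol)
  }
})

test_that("insertion promotes features shared by several surviving sets", {
  r1 <- c(s1 = 0.9, s2 = 0.8, j = 0.5, k = 0.4)
  sets <- list(s1 = c("s1", "j"), s2 = c("s2", "j"))
  out <- insertion_phase(sets, r1)
  expect_true("j" %in% names(out))
  expect_identical(out$j, c("j", "s1", "s2"))
  ## no cross-set sharing: output equals input
  sets2 <- list(s1 = c("s1", "j"), s2 = c("s2", "k"))
  expect_identical(insertion_phase(sets2, r1), sets2)
  expect_identical(insertion_phase(list(), r1), list())
})

test_that("greedy pipeline equals the hand-traced two-pass backward with insertion", {
  fx <- six_gene_codes()
  codes <- cbind(fx$codes, a2 = fx$codes[, "a"])
  y <- fx$y
  tab <- relevance_table(codes, y)
  r1 <- stats::setNames(tab$r1, tab$gene_id)
  p <- manual_partition(codes, y, list(c("a", "a2", "b"), c("c", "d"),
                                       c("e", "f")))
  eps <- 0.7   # admits (a,b), (a2,b) [r2 = 0.733] but not (a,a2) [r2 = r1(a) = 0.66]
  g_pre <- forward_phase(p, codes, y, eps, mode = "greedy")
  ## hand trace: greedy adds b to M_a and to M_a2 (both seeds are in
  ## Omega_1 and b follows each); backward keeps both pairs (complementary,
  ## no duplicate inside either set); insertion: b occurs in two sets, so
  ## M_b = {b, a, a2} is created; second backward removes a2 from M_b
  ## (redundant given a), leaving {b, a}
  expect_identical(g_pre, list(a = c("a", "b"), a2 = c("a2", "b")))
  b1 <- backward_phase(g_pre, codes, y)
  expect_identical(b1, list(a = c("a", "b"), a2 = c("a2", "b")))
  ins <- insertion_phase(b1, r1)
  expect_identical(sort(names(ins)), c("a", "a2", "b"))
  expect_identical(ins$b, c("b", "a", "a2"))
  b2 <- backward_phase(ins, codes, y)
  expect_identical(b2$b, c("b", "a"))
})

test_that("aggregation dissolves models in seed-relevance order, deduplicated", {
  r1 <- c(s1 = 0.9, a = 0.7, s2 = 0.6, b = 0.3)
  models <- list(s2 = c("s2", "a", "b"), s1 = c("s1", "a"))
  g <- aggregate_candidates(models, r1)
  expect_identical(g$gene_id, c("s1", "a", "s2", "b"))
  expect_identical(g$seed_set_index, c(1L, 1L, 2L, 2L))
  expect_identical(g$rank, 1:4)
  ## single model: candidate list equals its member list
  g1 <- aggregate_candidates(list(s1 = c("s1", "a")), r1)
  expect_identical(g1$gene_id, c("s1", "a"))
  expect_warning(g0 <- aggregate_candidates(list(), r1), "empty")
  expect_identical(nrow(g0), 0L)
})

test_that("aggregation matches an independent re-sort + dedup oracle", {
  set.seed(12)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:12)
    r1 <- stats::setNames(sort(runif(12), decreasing = TRUE), genes)
    seeds <- sample(genes, 3)
    models <- lapply(seeds, function(s)
      c(s, sample(setdiff(genes, s), sample(2:4, 1))))
    names(models) <- seeds
    g <- aggregate_candidates(models, r1)
    ord <- order(-r1[seeds], seeds)
    oracle <- unlist(models[ord], use.names = FALSE)
    oracle <- oracle[!duplicated(oracle)]
    expect_identical(g$gene_id, oracle)
  }
})

test_that("coding-identical duplicate copies never co-occur in one model", {
  ## the exact-zero redundancy criterion guarantees removal of copies whose
  ## discretized profiles coincide; jittered copies whose codes differ in
  ## some samples carry nonzero plug-in conditional information and may
  ## legitimately survive together
  for (sd in c(1, 5, 9)) {
    sim <- simulate_expression(planted_design(), seed = sd)
    fit <- tryCatch(suppressWarnings(suppressMessages(irda(sim$dataset))),
                    error = function(e) NULL)
    if (is.null(fit)) next
    codes <- discretize(sim$dataset$x)
    for (m in fit$models) {
      for (i in seq_along(m))
        for (j in seq_len(i - 1L))
          expect_gt(sum(codes[, m[i]] != codes[, m[j]]), 0L)
    }
  }
})

test_that("identical configuration and seed give identical fits", {
  sim1 <- simulate_expression(planted_design(), seed = 5)
  sim2 <- simulate_expression(planted_design(), seed = 5)
  expect_identical(sim1, sim2)
  f1 <- suppressWarnings(suppressMessages(irda(sim1$dataset)))
  f2 <- suppressWarnings(suppressMessages(irda(sim2$dataset)))
  expect_identical(f1$candidates, f2$candidates)
  expect_identical(f1$models, f2$models)
  expect_identical(f1$epsilon$value, f2$epsilon$value)
})

test_that("adding pure-noise genes rarely dislodges a recovered strong gene", {
  drops <- 0; comparable <- 0
  for (sd in 1:6) {
    sim <- simulate_expression(planted_design(n_genes = 300), seed = sd)
    base <- tryCatch(suppressWarnings(suppressMessages(irda(sim$dataset))),
                     error = function(e) NULL)
    if (is.null(base)) next
    set.seed(sd + 1000)
    extra <- matrix(rnorm(60 * 100), 60, 100,
                    dimnames = list(rownames(sim$dataset$x),
                                    sprintf("noise_extra%03d", 1:100)))
    aug <- tryCatch(suppressWarnings(suppressMessages(
      irda(cbind(sim$dataset$x, extra), sim$dataset$y))),
      error = function(e) NULL)
    if (is.null(aug)) next
    tr <- sim$truth
    classes <- lapply(tr$gene_id[tr$role == "strong"], function(s)
      c(s, tr$gene_id[!is.na(tr$parent) & tr$parent == s]))
    for (cl in classes) {
      if (any(cl %in% base$candidates$gene_id)) {
        comparable <- comparable + 1
        if (!any(cl %in% aug$candidates$gene_id)) drops <- drops + 1
      }
    }
  }
  expect_gte(comparable, 4)
  expect_lte(drops / comparable, 0.1)
})

test_that("planted strong-gene groups are recovered when the pipeline completes", {
  hits <- 0; runs <- 0
  for (sd in 1:8) {
    sim <- simulate_expression(planted_design(), seed = sd)
    fit <- tryCatch(suppressWarnings(suppressMessages(irda(sim$dataset))),
                    error = function(e) NULL)
    if (is.null(fit)) next
    runs <- runs + 1
    rec <- score_recovery(fit, sim$truth)
    hits <- hits + (rec$strong_recovered == rec$strong_total)
  }
  expect_gte(runs, 4)
  expect_gte(hits / runs, 0.7)
})
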