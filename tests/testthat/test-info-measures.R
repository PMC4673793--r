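test_that("discretization follows the mu +/- sigma/2 three-level rule", {
  ## gene engineered to have mu = 10, sigma = 4 exactly, containing the
  ## canonical points 7 (below 8), 10 (inside [8, 12]) and 13 (above 12)
  v <- c(7, 10, 13, 10 + sqrt(23), 10 - sqrt(23))
  expect_equal(mean(v), 10)
  expect_equal(sd(v), 4)
  expect_identical(as.vector(discretize(cbind(g1 = v))),
                   c(1L, 3L, 5L, 5L, 1L))
})

test_that("discretization boundaries are closed (both endpoints code 3)", {
  ## v = c(-10, -b, b, 10) with b = sqrt(20) has mean 0 and sample sd 2b,
  ## so the inner points sit exactly on the mu +/- sigma/2 boundaries
  b <- sqrt(20)
  v <- c(-10, -b, b, 10)
  expect_equal(sd(v) / 2, b)
  expect_identical(as.vector(discretize(cbind(g = v))), c(1L, 3L, 3L, 5L))
})

test_that("constant genes are coded 3 with a warning", {
  x <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  expect_warning(codes <- discretize(x), "constant")
  expect_identical(codes[, "g2"], c(3L, 3L, 3L))
})

test_that("entropy matches hand-computed plug-in values", {
  expect_identical(entropy(rep(1, 5)), 0)
  expect_equal(entropy(c(1, 1, 2, 2, 3, 3)), log2(3))
  expect_equal(entropy(c(1, 2, 2, 2)), -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(entropy(c(1, 2, 2, 2)), 0.811278124459, tolerance = 1e-10)
  expect_error(entropy(integer(0)), "empty")
})

test_that("conditional and joint entropy behave per definition", {
  x <- c(0, 0, 1, 1); y <- c(0, 1, 1, 1)
  expect_equal(conditional_entropy(x, x), 0)
  expect_equal(conditional_entropy(x, rep(7, 4)), entropy(x))
  ## enumerated joint counts: H(x|y) = 3/4 * H(1/3) ; H(y|x) = 1/2
  expect_equal(conditional_entropy(x, y), oracle_cond_entropy(x, y))
  expect_equal(conditional_entropy(x, y), 0.688721875541, tolerance = 1e-10)
  expect_equal(conditional_entropy(y, x), 0.5)
  expect_equal(joint_entropy(x, y), entropy(y) + conditional_entropy(x, y))
  expect_error(conditional_entropy(x, y[-1]), "mismatch")
})

test_that("mutual information: identity, independence, hand example", {
  x <- c(0, 0, 1, 1)
  expect_equal(mutual_information(x, x), 1)
  xf <- rep(c(0, 1), each = 4); yf <- rep(c(0, 1), 4)  # full factorial
  expect_equal(mutual_information(xf, yf), 0)
  y <- c(0, 1, 1, 1)
  expect_equal(mutual_information(x, y), entropy(y) - conditional_entropy(y, x))
  expect_equal(mutual_information(x, y), 0.311278124459, tolerance = 1e-10)
})

test_that("conditional mutual information: XOR synergy and degeneracies", {
  xf <- c(0, 0, 1, 1); wf <- c(0, 1, 0, 1)
  cf <- as.integer(xor(xf, wf))
  expect_equal(conditional_mutual_information(xf, cf, list(wf)), 1)
  expect_equal(mutual_information(xf, cf), 0)          # marginally blind
  ## y a deterministic function of z alone
  z <- c(1, 1, 2, 2, 3, 3); ydet <- c(5, 5, 6, 6, 7, 7)
  xr <- c(1, 2, 1, 2, 2, 1)
  expect_equal(conditional_mutual_information(xr, ydet, list(z)), 0)
  ## conditioning on an exact copy of x kills all information
  expect_equal(conditional_mutual_information(xf, cf, list(xf, wf)), 0)
  ## empty conditioning set degrades to MI
  expect_equal(conditional_mutual_information(xf, cf, NULL),
               mutual_information(xf, cf))
})

test_that("symmetrical uncertainty: limits and hand example", {
  x <- c(0, 0, 1, 1); y <- c(0, 1, 1, 1)
  expect_equal(symmetrical_uncertainty(x, x), 1)
  xf <- rep(c(0, 1), each = 4); yf <- rep(c(0, 1), 4)
  expect_equal(symmetrical_uncertainty(xf, yf), 0)
  expect_equal(symmetrical_uncertainty(x, y),
               2 * 0.311278124459 / (1 + 0.811278124459), tolerance = 1e-9)
  expect_warning(su0 <- symmetrical_uncertainty(rep(1, 4), rep(2, 4)),
                 "constant")
  expect_equal(su0, 0)
})

test_that("joint symmetrical uncertainty: identity, independence, XOR", {
  b <- c(0, 0, 1, 1)
  expect_equal(joint_symmetrical_uncertainty(b, b, b), 1)
  x1 <- rep(c(0, 1), each = 4); x2 <- rep(c(0, 1), 4)
  yind <- c(0, 1, 0, 1, 1, 0, 1, 0)   # balanced within every (x1,x2) cell
  x1f <- rep(x1, 2); x2f <- rep(x2, 2); yf <- c(yind, 1 - yind)
  expect_equal(joint_symmetrical_uncertainty(x1f, x2f, yf), 0)
  xf <- c(0, 0, 1, 1); wf <- c(0, 1, 0, 1)
  cf <- as.integer(xor(xf, wf))
  expect_equal(joint_symmetrical_uncertainty(xf, wf, cf), 2 / 3)
})

test_that("all measures agree with the brute-force oracle on random vectors", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    x <- rand_discrete(n, sample(2:4, 1))
    y <- rand_discrete(n, sample(2:4, 1))
    z1 <- rand_discrete(n, 2)
    z2 <- rand_discrete(n, 3)
    expect_equal(entropy(x), oracle_entropy(x), tolerance = 1e-12)
    expect_equal(joint_entropy(x, y), oracle_joint_entropy(x, y), tolerance = 1e-12)
    expect_equal(conditional_entropy(x, y), oracle_cond_entropy(x, y), tolerance = 1e-12)
    expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
    expect_equal(conditional_mutual_information(x, y, list(z1, z2)),
                 oracle_cmi(x, y, list(z1, z2)), tolerance = 1e-12)
    expect_equal(suppressWarnings(symmetrical_uncertainty(x, y)),
                 oracle_su(x, y), tolerance = 1e-12)
    expect_equal(joint_symmetrical_uncertainty(x, z1, y),
                 oracle_joint_su(x, z1, y), tolerance = 1e-12)
  }
})

test_that("information identities hold on random inputs", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:15, 1)
    x <- rand_discrete(n, 3); y <- rand_discrete(n, 3); z <- rand_discrete(n, 2)
    ## three-way consistency
    expect_equal(mutual_information(x, y),
                 entropy(x) + entropy(y) - joint_entropy(x, y),
                 tolerance = 1e-12)
    ## chain rule for CMI
    zc <- z
    expect_equal(conditional_mutual_information(x, y, list(z)),
                 oracle_cond_entropy(x, paste(zc)) -
                   oracle_cond_entropy(x, paste(y, zc)),
                 tolerance = 1e-12)
    ## SU invariant under state relabeling and log base (base drops out)
    relab <- c(10, 20, 30)[x]
    expect_equal(symmetrical_uncertainty(relab, y),
                 symmetrical_uncertainty(x, y), tolerance = 1e-12)
  }
})
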