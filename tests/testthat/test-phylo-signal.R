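# literal transcription of the K formula, kept separate from the package
# implementation as an oracle
oracle_k <- function(V, x) {
  n <- length(x)
  Vinv <- solve(V)
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Vinv %*% x) / as.numeric(t(one) %*% Vinv %*% one)
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Vinv %*% (x - a)) / (n - 1)
  expected <- (sum(diag(V)) - n / as.numeric(t(one) %*% Vinv %*% one)) /
    (n - 1)
  (mse0 / mse) / expected
}

test_that("Grafen heights give the expected branch lengths", {
  two <- grafen_branch_lengths(ape::read.tree(text = "(a,b);"))
  expect_equal(two$edge.length, c(1, 1))

  bal4 <- grafen_branch_lengths(ape::read.tree(text = "((a,b),(c,d));"))
  # root height 1, cherry heights (2-1)/(4-1) = 1/3
  expect_equal(sort(unique(round(bal4$edge.length, 10))),
               round(c(1 / 3, 2 / 3), 10))

  cat3 <- grafen_branch_lengths(ape::read.tree(text = "((a,b),c);"))
  # heights 1 and 1/2: branches {1/2, 1/2, 1/2, 1}
  expect_equal(sort(cat3$edge.length), c(0.5, 0.5, 0.5, 1))
})

test_that("near-zero branches are raised to epsilon and no further", {
  tr <- ape::read.tree(text = "((a:0,b:0.5):0.2,c:0.7);")
  rep1 <- repair_near_zero(tr, 1e-6)
  expect_equal(sort(rep1$edge.length), sort(c(0.2, 1e-6, 0.5, 0.7)))
  # all lengths already above the floor: identity
  expect_equal(repair_near_zero(rep1, 1e-9), rep1)
  expect_error(repair_near_zero(tr, 0), "epsilon")
  # height perturbation is bounded by epsilon per repaired branch
  h0 <- max(ape::node.depth.edgelength(tr))
  h1 <- max(ape::node.depth.edgelength(rep1))
  expect_lte(abs(h1 - h0), 1e-6)
})

test_that("the phylogenetic covariance matches shared path lengths", {
  star <- ape::stree(5, "star")
  star$edge.length <- rep(1, 5)
  expect_equal(unname(phylo_vcv(star)), diag(5))

  sis <- ape::read.tree(text = "((a:0.1,b:0.1):0.9,c:1);")
  V <- phylo_vcv(sis)
  expect_equal(V["a", "b"], 0.9)
  expect_equal(V["a", "c"], 0)
  expect_equal(diag(V), c(a = 1, b = 1, c = 1))

  # random 8-tip tree against a brute-force pairwise-MRCA path sum
  set.seed(3)
  tr <- ape::rtree(8)
  V <- phylo_vcv(tr)
  root <- length(tr$tip.label) + 1
  depth <- ape::node.depth.edgelength(tr)
  mr <- ape::mrca(tr)
  for (i in 1:8) for (j in 1:8) {
    expected <- if (i == j) depth[i] else depth[mr[i, j]]
    expect_equal(unname(V[tr$tip.label[i], tr$tip.label[j]]), expected,
                 tolerance = 1e-12)
  }
})

test_that("Blomberg's K is exact on stars and matches the formula oracle", {
  star <- ape::stree(9, "star")
  star$edge.length <- rep(1, 9)
  set.seed(5)
  x <- setNames(rnorm(9), star$tip.label)
  expect_equal(blomberg_k(star, x), 1, tolerance = 1e-9)

  tr4 <- ape::read.tree(text = "((a:0.3,b:0.3):0.7,(c:0.6,d:0.6):0.4);")
  x4 <- c(a = 1.2, b = 0.8, c = -0.5, d = -1.1)
  V <- phylo_vcv(tr4)
  expect_equal(blomberg_k(tr4, x4), oracle_k(V, x4[rownames(V)]),
               tolerance = 1e-12)

  # independent cross-check against the reference implementation
  set.seed(11)
  tr <- grafen_branch_lengths(ape::rtree(15, br = NULL))
  xt <- setNames(rnorm(15), tr$tip.label)
  expect_equal(blomberg_k(tr, xt),
               as.numeric(phytools::phylosig(tr, xt, method = "K")),
               tolerance = 1e-8)
})

test_that("K is invariant to affine traits and branch rescaling", {
  set.seed(9)
  tr <- grafen_branch_lengths(ape::rtree(12, br = NULL))
  x <- setNames(rnorm(12), tr$tip.label)
  k <- blomberg_k(tr, x)
  expect_equal(blomberg_k(tr, 3.7 - 2.2 * x), k, tolerance = 1e-9)
  scaled <- tr
  scaled$edge.length <- tr$edge.length * 17
  expect_equal(blomberg_k(scaled, x), k, tolerance = 1e-9)
})

test_that("pruning inside blomberg_k equals computing on a pruned tree", {
  set.seed(2)
  tr <- grafen_branch_lengths(ape::rtree(10, br = NULL))
  keep <- tr$tip.label[1:6]
  x <- setNames(rnorm(6), keep)
  pruned <- ape::keep.tip(tr, keep)
  expect_equal(blomberg_k(tr, x), blomberg_k(pruned, x), tolerance = 1e-12)
  expect_error(blomberg_k(pruned, c(setNames(1, "nope"), x)), "absent")
})

test_that("permutation p-values behave and agree with enumeration", {
  set.seed(4)
  tr <- grafen_branch_lengths(ape::rtree(6, br = NULL))
  x <- setNames(c(2.1, 1.9, 2.2, -1.8, -2.0, 0.1), tr$tip.label)
  res <- permutation_test(tr, x, n_permutations = 2000, seed = 1)
  expect_gte(res$p_value, 1 / 2001)

  # exhaustive permutation distribution on the same 6-tip instance
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  k_all <- apply(perms, 1, function(p) {
    blomberg_k(tr, setNames(unname(x)[p], names(x)))
  })
  p_exact <- mean(k_all >= blomberg_k(tr, x))
  expect_lt(abs(res$p_value - p_exact), 3 * sqrt(p_exact / 2000) + 1e-3)

  # clade-structured trait on 16 tips: strong signal
  tr16 <- grafen_branch_lengths(ape::read.tree(
    text = paste0("(((a1,a2),(a3,a4)),(((b1,b2),(b3,b4)),",
                  "(((c1,c2),(c3,c4)),((d1,d2),(d3,d4)))));")))
  clade <- setNames(rep(c(10, 0, 0, 0), each = 4) + rnorm(16, 0, 0.1),
                    tr16$tip.label)
  strong <- permutation_test(tr16, clade, n_permutations = 1000, seed = 2)
  expect_lte(strong$p_value, 0.01)

  # determinism and the constant-trait edge case
  expect_identical(permutation_test(tr, x, 200, seed = 9)$p_value,
                   permutation_test(tr, x, 200, seed = 9)$p_value)
  const <- setNames(rep(1.5, 6), tr$tip.label)
  expect_warning(pc <- permutation_test(tr, const, 100, seed = 1),
                 "constant")
  expect_equal(pc$p_value, 1)
})
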