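#' Assign Grafen branch lengths
#'
#' Gives a topology branch lengths from Grafen node heights: each internal
#' node's height is proportional to its number of descendant tips minus one,
#' normalised so the root has height 1 and tips height 0. Unrooted trees are
#' midpoint-rooted first (a root is required for height assignment), with a
#' message.
#'
#' @param tree a `phylo` object with >= 2 tips.
#' @return the tree with positive branch lengths.
#' @export
grafen_branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2)
  if (!ape::is.rooted(tree)) {
    message("unrooted input tree: midpoint-rooting before height assignment")
    if (is.null(tree$edge.length)) {
      tree <- ape::compute.brlen(ape::multi2di(tree), method = "Grafen")
    }
    tree <- phangorn::midpoint(tree)
  }
  ape::compute.brlen(tree, method = "Grafen", power = 1)
}

#' Raise near-zero branch lengths to a small constant
#'
#' Branches shorter than `epsilon` are set to `epsilon`; others are left
#' untouched. The default is a small fraction of the tree height, so the
#' repair cannot distort the phylogenetic covariance appreciably while
#' keeping it non-singular.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param epsilon positive length floor; default `1e-6 *` max root-to-tip
#'   height.
#' @return repaired tree.
#' @export
repair_near_zero <- function(tree, epsilon = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (is.null(epsilon)) {
    epsilon <- 1e-6 * max(ape::node.depth.edgelength(tree))
  }
  if (epsilon <= 0) stop("epsilon must be > 0")
  tree$edge.length[tree$edge.length < epsilon] <- epsilon
  tree
}

#' Phylogenetic covariance matrix
#'
#' The Brownian-motion tip covariance: entry (i, j) is the shared
#' root-to-MRCA path length of tips i and j; the diagonal holds root-to-tip
#' distances.
#'
#' @param tree rooted `phylo` with positive branch lengths.
#' @return symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("tree needs positive branch lengths; see grafen_branch_lengths() ",
         "and repair_near_zero()")
  }
  ape::vcv(tree)
}

#' Blomberg's K
#'
#' Phylogenetic signal of a continuous trait: the ratio of the observed
#' mean squared error about the phylogenetically corrected mean to the
#' GLS mean squared error, standardised by its Brownian-motion expectation,
#' so K = 1 matches Brownian evolution on the tree and K < 1 indicates
#' weaker-than-Brownian resemblance among relatives. With
#' `a = (1'V^-1 x)/(1'V^-1 1)`,
#' `K = [(x-a)'(x-a) / (x-a)'V^-1(x-a)] / [(tr V - n/(1'V^-1 1)) / (n-1)]`.
#'
#' The tree is pruned to the named trait values before computation.
#'
#' @param tree rooted `phylo` with positive branch lengths.
#' @param trait named numeric vector (names are tip labels).
#' @return scalar K >= 0.
#' @export
blomberg_k <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(trait)))
  missing_tips <- setdiff(names(trait), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("trait names absent from tree: ",
         paste(missing_tips, collapse = ", "))
  }
  if (length(trait) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, names(trait))
  }
  V <- phylo_vcv(tree)
  x <- trait[rownames(V)]
  n <- length(x)
  Vinv <- tryCatch(solve(V), error = function(e) {
    stop("phylogenetic covariance matrix is singular; raise near-zero ",
         "branches with repair_near_zero()")
  })
  one <- rep(1, n)
  denom1 <- drop(one %*% Vinv %*% one)
  a <- drop(one %*% Vinv %*% x) / denom1
  d <- x - a
  mse0 <- sum(d * d) / (n - 1)
  mse <- drop(d %*% Vinv %*% d) / (n - 1)
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for phylogenetic signal
#'
#' One-sided test of Blomberg's K against the null of no signal: trait
#' values are shuffled uniformly across tips and
#' `p = (1 + #\{K_perm >= K_obs\}) / (1 + n_permutations)` (add-one
#' correction, so the smallest attainable p with 1000 permutations is
#' 1/1001).
#'
#' @param tree rooted `phylo` with positive branch lengths.
#' @param trait named numeric vector.
#' @param n_permutations number of permutations (>= 1); default 1000.
#' @param seed integer seed (shuffles are deterministic under it).
#' @return object of class `phylo_signal_result`: `K`, `p_value`,
#'   `n_permutations`, `seed`, `n_tips`.
#' @export
permutation_test <- function(tree, trait, n_permutations = 1000L, seed = 1L) {
  stopifnot(n_permutations >= 1)
  k_obs <- blomberg_k(tree, trait)
  if (stats::var(trait) == 0) {
    warning("constant trait: all permutations identical, p = 1")
    p <- 1
  } else {
    if (length(trait) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, names(trait))
    }
    set.seed(as.integer(seed))
    labs <- names(trait)
    k_perm <- vapply(seq_len(n_permutations), function(i) {
      perm <- trait[sample.int(length(trait))]
      names(perm) <- labs
      blomberg_k(tree, perm)
    }, 0)
    p <- (1 + sum(k_perm >= k_obs)) / (1 + n_permutations)
  }
  structure(list(K = k_obs, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 n_tips = length(trait)),
            class = "phylo_signal_result")
}

#' @export
print.phylo_signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f, P = %.4g (%d tips, %d permutations)\n",
              x$K, x$p_value, x$n_tips, x$n_permutations))
  invisible(x)
}
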