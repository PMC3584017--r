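# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration or naive counting, never by calling the
# package code paths they check.

# per-column p-distance counter (pairwise deletion, unambiguous bases only)
oracle_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] != cb[ok])
}

# affine-gap global alignment score by an independent three-state DP in R
# (gap of length L costs go + (L-1)*ge; gap-state switches allowed)
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               go = -4, ge = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  if (m > 0) X[1, 2:(m + 1)] <- go + (seq_len(m) - 1) * ge
  if (n > 0) Y[2:(n + 1), 1] <- go + (seq_len(n) - 1) * ge
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(max(M[i + 1, j], Y[i + 1, j]) + go,
                             X[i + 1, j] + ge)
      Y[i + 1, j + 1] <- max(max(M[i, j + 1], X[i, j + 1]) + go,
                             Y[i, j + 1] + ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# monophyly by edge removal: S is a clade iff deleting some edge leaves the
# component containing S holding exactly S among the tips (graph search,
# independent of any bipartition utility)
oracle_monophyletic <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  target <- sort(match(tips, tree$tip.label))
  if (length(target) <= 1 || length(target) == ntip) return(TRUE)
  edges <- tree$edge
  for (e in seq_len(nrow(edges))) {
    rem <- edges[-e, , drop = FALSE]
    comp <- edges[e, 2]
    repeat {
      hit <- rem[, 1] %in% comp | rem[, 2] %in% comp
      newc <- union(comp, as.vector(rem[hit, ]))
      if (length(newc) == length(comp)) break
      comp <- newc
    }
    side <- sort(intersect(comp, seq_len(ntip)))
    other <- sort(setdiff(seq_len(ntip), side))
    if (identical(side, target) || identical(other, target)) return(TRUE)
  }
  FALSE
}

# ordinary-least-squares branch-length fit of a distance matrix on a fixed
# topology; returns the residual sum of squares
oracle_ols_rss <- function(tree, dm) {
  labs <- rownames(dm)
  prs <- utils::combn(length(labs), 2)
  nedge <- nrow(tree$edge)
  X <- matrix(0, ncol(prs), nedge)
  dvec <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- match(labs[prs[1, k]], tree$tip.label)
    j <- match(labs[prs[2, k]], tree$tip.label)
    path <- ape::nodepath(tree, i, j)
    for (q in seq_len(length(path) - 1)) {
      e <- which((tree$edge[, 1] == path[q] & tree$edge[, 2] == path[q + 1]) |
                 (tree$edge[, 2] == path[q] & tree$edge[, 1] == path[q + 1]))
      X[k, e] <- 1
    }
    dvec[k] <- dm[labs[prs[1, k]], labs[prs[2, k]]]
  }
  fit <- stats::lm.fit(X, dvec)
  sum(fit$residuals^2)
}

# exhaustive minimum-RSS topology search over all unrooted binary topologies
oracle_best_topology <- function(dm) {
  tops <- phangorn::allTrees(nrow(dm), rooted = FALSE,
                             tip.label = rownames(dm))
  rss <- vapply(tops, oracle_ols_rss, numeric(1), dm = dm)
  tops[[which.min(rss)]]
}

# exact signed-rank p-value by full 2^n sign enumeration (midranks,
# zero differences dropped before calling)
oracle_signrank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% rk)
  eps <- 1e-9
  p_ge <- mean(Ws >= W - eps)
  p_le <- mean(Ws <= W + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# random additive tree + its exact cophenetic distance matrix
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[paste0("t", seq_len(n)), paste0("t", seq_len(n))]
  list(tree = tr, dm = dm)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# small random collection for property tests
random_collection <- function(seed, n_genera = 3, spg = 2, acc = c(2, 1, 3)) {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = n_genera, species_per_genus = spg,
    accessions_per_species = acc,
    locus_lengths = c(locusA = 120L),
    inter_divergence = 0.08, intra_divergence = 0.01, seed = seed))
  sd$collections[[1]]
}
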