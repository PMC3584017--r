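#' Neighbor-joining tree from a p-distance matrix
#'
#' Classical Saitou-Nei neighbor joining (via \pkg{ape}). Missing entries
#' (pairs without comparable sites under pairwise deletion) are imputed as
#' the maximum observed distance, with a warning; this is conservative
#' against spurious monophyly. Negative branch lengths are clamped to zero
#' with the difference transferred to the adjacent branch so that pairwise
#' path lengths are preserved.
#'
#' @param dm Symmetric distance matrix with at least three rows.
#' @return An unrooted `phylo` tree with tips labelled by sample id.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("need at least three taxa")
  dm <- impute_missing(dm, warn = TRUE)
  tr <- ape::nj(as.dist(dm))
  clamp_negative_edges(tr)
}

impute_missing <- function(dm, warn = FALSE) {
  if (anyNA(dm)) {
    mx <- max(dm, na.rm = TRUE)
    if (warn)
      warning(sprintf("imputing %d missing distance(s) as the maximum (%.4f)",
                      sum(is.na(dm)) / 2, mx))
    dm[is.na(dm)] <- mx
    diag(dm) <- 0
  }
  dm
}

clamp_negative_edges <- function(tr) {
  # set negative branch lengths to 0 and move the (negative) difference to
  # the sister branch, preserving tip-to-tip path lengths through the parent
  if (is.null(tr$edge.length)) return(tr)
  for (e in order(tr$edge.length)) {
    if (tr$edge.length[e] >= 0) next
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Test whether a set of tips is monophyletic on an unrooted tree
#'
#' A leaf set is monophyletic when some edge bipartition of the unrooted
#' tree separates exactly that set from all remaining leaves.
#'
#' @param tree A `phylo` tree.
#' @param tips Character vector of tip labels (or tip indices).
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, tips) {
  if (is.character(tips)) tips <- match(tips, tree$tip.label)
  if (anyNA(tips)) stop("unknown tip labels")
  ntip <- length(tree$tip.label)
  k <- length(tips)
  if (k <= 1L || k == ntip) return(TRUE)
  target <- sort(unique(tips))
  parts <- ape::prop.part(tree)
  for (p in parts) {
    if (length(p) == k && all(sort(p) == target)) return(TRUE)
    if (length(p) == ntip - k && !any(p %in% target)) return(TRUE)
  }
  FALSE
}

#' Bootstrap monophyly support per species
#'
#' Nonparametric bootstrap over alignment columns: each replicate resamples
#' columns with replacement, recomputes the p-distance matrix under
#' pairwise deletion, rebuilds the NJ tree, and scores each multi-accession
#' species as monophyletic or not. Support is the percentage of replicates
#' in which the species forms a clade. Replicates are reproducible given
#' `seed` (replicate `r` reseeds at `seed + r`, so results do not depend on
#' execution order).
#'
#' @param aln A [barcode_alignment()].
#' @param species_of Named character vector mapping sample id to species.
#' @param n_reps Number of bootstrap replicates (surveys conventionally use
#'   1000).
#' @param seed Integer RNG seed.
#' @param support_cutoff Support percentage (inclusive) required to call a
#'   species resolved; the conventional cutoff is 50.
#' @param mode `"support_and_original"` (default): resolved requires
#'   monophyly in the original tree *and* support at the cutoff;
#'   `"support_only"` uses the support alone.
#' @param ambiguity Passed to [distance_matrix()].
#' @param keep_trees If `TRUE`, the replicate trees are attached as
#'   attribute `"trees"` (a `multiPhylo`), e.g. for a strict consensus.
#' @return A data frame of class `monophyly_result` with one row per
#'   multi-accession species: `species`, `n_accessions`,
#'   `monophyletic_in_original`, `bootstrap_support`, `resolved`.
#' @export
bootstrap_support <- function(aln, species_of, n_reps = 1000L, seed = 1L,
                              support_cutoff = 50,
                              mode = c("support_and_original", "support_only"),
                              ambiguity = c("missing", "partial-match"),
                              keep_trees = FALSE) {
  mode <- match.arg(mode)
  ambiguity <- match.arg(ambiguity)
  partial <- ambiguity == "partial-match"
  if (length(aln$rows) < 3L) stop("need at least three rows")
  sp <- species_of[aln$ids]
  if (any(is.na(sp))) stop("species_of is missing some sample ids")
  counts <- table(sp)
  multi <- names(counts)[counts >= 2]
  if (length(multi) == 0L) stop("no multi-accession species")
  tip_sets <- lapply(multi, function(s) aln$ids[sp == s])
  rows <- unname(aln$rows)
  L <- aln$length
  d0 <- pdist_matrix_cpp(rows, partial)
  dimnames(d0) <- list(aln$ids, aln$ids)
  tr0 <- ape::nj(as.dist(impute_missing(d0)))
  tr0 <- clamp_negative_edges(tr0)
  mono0 <- vapply(tip_sets, function(tp) is_monophyletic(tr0, tp), logical(1))
  hits <- integer(length(multi))
  trees <- if (keep_trees) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    set.seed((seed + r) %% .Machine$integer.max)
    cols <- sample.int(L, L, replace = TRUE)
    d <- pdist_matrix_cpp(rows, partial, cols)
    dimnames(d) <- list(aln$ids, aln$ids)
    tr <- ape::nj(as.dist(impute_missing(d)))
    hits <- hits + vapply(tip_sets, function(tp) is_monophyletic(tr, tp),
                          logical(1))
    if (keep_trees) trees[[r]] <- tr
  }
  support <- 100 * hits / n_reps
  resolved <- if (mode == "support_and_original")
    mono0 & support >= support_cutoff else support >= support_cutoff
  out <- data.frame(species = multi,
                    n_accessions = as.integer(counts[multi]),
                    monophyletic_in_original = mono0,
                    bootstrap_support = support,
                    resolved = resolved,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "original_tree") <- tr0
  attr(out, "tip_sets") <- setNames(tip_sets, multi)
  attr(out, "support_cutoff") <- support_cutoff
  if (keep_trees) {
    class(trees) <- "multiPhylo"
    attr(out, "trees") <- trees
  }
  class(out) <- c("monophyly_result", "data.frame")
  out
}

#' Species resolution percentage from bootstrap monophyly results
#'
#' @param results A `monophyly_result` data frame from
#'   [bootstrap_support()].
#' @return Percentage (0-100) of multi-accession species resolved.
#' @export
species_resolution_tree <- function(results) {
  if (NROW(results) == 0L) stop("empty results")
  100 * sum(results$resolved) / nrow(results)
}

#' Strict consensus of bootstrap replicate trees
#'
#' @param trees A `multiPhylo` list of trees (e.g. attribute `"trees"` of
#'   [bootstrap_support()] run with `keep_trees = TRUE`).
#' @return The strict consensus `phylo` tree.
#' @export
strict_consensus <- function(trees) {
  ape::consensus(trees, p = 1)
}

#' Write a tree with bootstrap supports as Newick
#'
#' Internal node labels are set from per-species bootstrap supports at the
#' nodes whose clade is exactly that species' accession set in the original
#' NJ tree; other internal nodes are left unlabelled.
#'
#' @param results A `monophyly_result` from [bootstrap_support()].
#' @param path Output Newick path.
#' @return Invisibly, the annotated tree.
#' @export
write_support_tree <- function(results, path) {
  tr <- attr(results, "original_tree")
  tip_sets <- attr(results, "tip_sets")
  if (is.null(tr)) stop("results carry no original tree")
  ntip <- length(tr$tip.label)
  parts <- ape::prop.part(tr)
  labs <- rep("", tr$Nnode)
  for (i in seq_len(nrow(results))) {
    target <- sort(match(tip_sets[[results$species[i]]], tr$tip.label))
    for (k in seq_along(parts)) {
      if (length(parts[[k]]) == length(target) &&
          all(sort(parts[[k]]) == target)) {
        labs[k] <- sprintf("%.0f", results$bootstrap_support[i])
      }
    }
  }
  tr$node.label <- labs
  ape::write.tree(tr, file = path)
  invisible(tr)
}
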