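test_that("nj_tree recovers additive four-taxon trees exactly", {
  # quartet ((A:1,B:2):1,(C:3,D:1)) -> pairwise path lengths
  dm <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # additive input: the NJ tree reproduces the matrix exactly
  co <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(co, dm, tolerance = 1e-10)
  # and AB|CD is the split: A-B path avoids the C-D side
  expect_true(oracle_monophyletic(tr, c("A", "B")))
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  expect_true(same_topology(tr, truth))
})

test_that("nj_tree needs three taxa and imputes missing entries", {
  dm2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(dm2), "three taxa")
  dm3 <- matrix(c(0, .1, NA, .1, 0, .3, NA, .3, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- nj_tree(dm3), "imputing")
  expect_equal(sort(tr$tip.label), letters[1:3])
  expect_true(all(tr$edge.length >= 0))
})

test_that("five-taxon additive matrices are recovered against exhaustive search", {
  for (seed in 1:10) {
    case <- random_additive_case(5, seed = 100 + seed)
    got <- nj_tree(case$dm)
    expect_true(same_topology(got, case$tree), info = paste("seed", seed))
    oracle <- oracle_best_topology(case$dm)
    expect_true(same_topology(got, oracle), info = paste("seed", seed))
  }
})

test_that("monophyly matches the edge-removal oracle on random trees", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    k <- sample(2:(n - 2), 1)
    tips <- sample(tr$tip.label, k)
    got <- is_monophyletic(tr, tips)
    expect_equal(got, oracle_monophyletic(tr, tips),
                 info = sprintf("i=%d n=%d k=%d", i, n, k))
  }
})

mk_aln <- function(rows) barcode_alignment(rows, "toy")

test_that("bootstrap support separates clean species and collapses interleaved ones", {
  a <- paste(rep("A", 40), collapse = "")
  c40 <- paste(rep("C", 40), collapse = "")
  g40 <- paste(rep("G", 40), collapse = "")
  rows <- c(x1 = a, x2 = a, y1 = c40, y2 = c40, z1 = g40, z2 = g40)
  sp <- setNames(c("X x", "X x", "Y y", "Y y", "Z z", "Z z"), names(rows))
  bs <- bootstrap_support(mk_aln(rows), sp, n_reps = 60, seed = 5)
  expect_equal(bs$bootstrap_support, rep(100, 3))
  expect_true(all(bs$resolved))
  expect_equal(species_resolution_tree(bs), 100)

  # identical sequences shared across two species: neither can be a clade
  mixed <- c(x1 = a, x2 = c40, y1 = a, y2 = c40, z1 = g40, z2 = g40)
  spm <- setNames(c("X x", "X x", "Y y", "Y y", "Z z", "Z z"), names(mixed))
  bsm <- bootstrap_support(mk_aln(mixed), spm, n_reps = 60, seed = 5)
  expect_equal(bsm$bootstrap_support[bsm$species %in% c("X x", "Y y")],
               c(0, 0))
  expect_false(any(bsm$resolved[bsm$species %in% c("X x", "Y y")]))
})

test_that("bootstrap support is reproducible and order-invariant", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 2, species_per_genus = 2, accessions_per_species = 2,
    locus_lengths = c(L = 150L), inter_divergence = 0.08,
    intra_divergence = 0.01, seed = 31))
  coll <- sd$collections$L
  aln <- progressive_align(coll)
  sp <- setNames(coll$species, coll$sample_id)
  b1 <- bootstrap_support(aln, sp, n_reps = 40, seed = 77)
  b2 <- bootstrap_support(aln, sp, n_reps = 40, seed = 77)
  expect_equal(b1$bootstrap_support, b2$bootstrap_support)

  perm <- sample(length(aln$rows))
  aln_p <- barcode_alignment(aln$rows[perm], aln$label)
  b3 <- bootstrap_support(aln_p, sp, n_reps = 40, seed = 77)
  m1 <- setNames(b1$bootstrap_support, b1$species)
  m3 <- setNames(b3$bootstrap_support, b3$species)
  expect_equal(m3[names(m1)], m1)
})

test_that("tree resolution percentage applies the inclusive 50% cutoff", {
  res <- data.frame(species = paste0("s", 1:5),
                    n_accessions = 2L,
                    monophyletic_in_original = TRUE,
                    bootstrap_support = c(100, 80, 50, 49, 10),
                    resolved = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(species_resolution_tree(res), 60)
  res$resolved <- res$bootstrap_support >= 50
  expect_equal(species_resolution_tree(res), 60)  # 50 counts, 49 does not
  res_all49 <- transform(res, bootstrap_support = 49, resolved = FALSE)
  expect_equal(species_resolution_tree(res_all49), 0)
  expect_error(species_resolution_tree(res[0, ]), "empty")
})

test_that("support trees and strict consensus can be written", {
  a <- paste(rep("A", 30), collapse = "")
  t30 <- paste(rep("T", 30), collapse = "")
  g30 <- paste(rep("G", 30), collapse = "")
  rows <- c(x1 = a, x2 = a, y1 = t30, y2 = t30, z1 = g30)
  sp <- setNames(c("X x", "X x", "Y y", "Y y", "Z z"), names(rows))
  bs <- bootstrap_support(mk_aln(rows), sp, n_reps = 25, seed = 2,
                          keep_trees = TRUE)
  nwk <- tempfile(fileext = ".nwk")
  write_support_tree(bs, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, names(rows))
  expect_true(any(back$node.label == "100"))
  cons <- strict_consensus(attr(bs, "trees"))
  expect_s3_class(cons, "phylo")
  expect_setequal(cons$tip.label, names(rows))
})
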