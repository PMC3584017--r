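test_that("p-distance follows pairwise deletion semantics", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "AGGT"), 1 / 3)   # gap column dropped
  expect_error(p_distance("ACGT", "ACG"), "equal length")
  # ambiguity codes are missing by default, comparable under partial match
  expect_equal(p_distance("ACGR", "ACGA"), 0)            # R excluded: 3 sites
  expect_equal(p_distance("ACGR", "ACGA", ambiguity = "partial-match"), 0)
  expect_equal(p_distance("RRRR", "AAAA"), NA_real_)
  expect_equal(p_distance("ACGR", "ACGC", ambiguity = "partial-match"), 0.25)
  expect_equal(p_distance("NNNN", "ACGT"), NA_real_)
})

test_that("p-distance equals the per-column brute-force counter", {
  set.seed(99)
  alphabet <- c("A", "C", "G", "T", "-", "N", "R", "Y")
  for (k in 1:300) {
    L <- sample(5:60, 1)
    a <- paste(sample(alphabet, L, TRUE, prob = c(rep(.2, 4), .1, .05, .025, .025)),
               collapse = "")
    b <- paste(sample(alphabet, L, TRUE, prob = c(rep(.2, 4), .1, .05, .025, .025)),
               collapse = "")
    expect_identical(p_distance(a, b), oracle_pdist(a, b),
                     info = paste(a, b))
  }
})

test_that("distance_matrix is symmetric, zero-diagonal and flags missing", {
  rows <- c(r1 = "ACGTACGT", r2 = "ACGTACGT")
  dm <- distance_matrix(rows)
  expect_equal(unclass(dm), matrix(0, 2, 2, dimnames = list(names(rows), names(rows))),
               ignore_attr = TRUE)

  rows3 <- c(a = "ACGTAC", b = "ACGAAC", c = "TTTAAC")
  dm3 <- distance_matrix(rows3)
  expect_equal(dm3["a", "b"], oracle_pdist("ACGTAC", "ACGAAC"))
  expect_equal(dm3["a", "c"], oracle_pdist("ACGTAC", "TTTAAC"))
  expect_equal(dm3["b", "c"], oracle_pdist("ACGAAC", "TTTAAC"))
  expect_equal(dm3, t(dm3))

  disjoint <- c(x = "ACGT----", y = "----ACGT", z = "ACGTACGT")
  expect_warning(dmx <- distance_matrix(disjoint), "no comparable site")
  expect_true(is.na(dmx["x", "y"]))
  expect_false(anyNA(dmx["x", "z"]))
})

test_that("distance_matrix agrees with ape's raw pairwise-deletion distances", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 2, species_per_genus = 2, accessions_per_species = 2,
    locus_lengths = c(L = 300L), inter_divergence = 0.1,
    intra_divergence = 0.02, seed = 4))
  aln <- progressive_align(sd$collections$L)
  dm <- distance_matrix(aln)
  bin <- ape::as.DNAbin(setNames(strsplit(tolower(aln$rows), ""), aln$ids))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unclass(dm), ref[rownames(dm), colnames(dm)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("site classes implement the variable / parsimony-informative rules", {
  same4 <- setNames(rep("ACGTACGTAC", 4), paste0("s", 1:4))
  sc0 <- site_classes(same4)
  expect_equal(sc0$pct_variable, 0)
  expect_equal(sc0$pct_pic, 0)

  # column {A,A,C,C} is PIC; {A,A,A,C} variable only
  cols <- rbind(c("A", "A"), c("A", "A"), c("C", "A"), c("C", "C"))
  rows <- setNames(apply(cols, 1, paste, collapse = ""), paste0("s", 1:4))
  sc <- site_classes(rows)
  expect_equal(sc$n_variable, 2L)
  expect_equal(sc$n_pic, 1L)
})

test_that("pic percentage never exceeds variable percentage", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 6 * 40, TRUE,
                       prob = c(rep(.22, 4), .08, .04)), nrow = 6)
    rows <- setNames(apply(m, 1, paste, collapse = ""), paste0("s", 1:6))
    sc <- site_classes(rows)
    expect_lte(sc$pct_pic, sc$pct_variable)
    expect_lte(sc$pct_variable, 100)
  }
})

test_that("divergence summary splits intra and inter pairs correctly", {
  rows <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA",
            b1 = "AAAAAAAAAC", b2 = "AAAAAAAAAC")
  sp <- c(a1 = "X x", a2 = "X x", b1 = "Y y", b2 = "Y y")
  dm <- distance_matrix(rows)
  dv <- divergence_summary(dm, sp)
  expect_equal(dv$mean_intra, 0)
  expect_equal(dv$mean_inter, 0.1)
  expect_length(dv$intra, 2L)
  expect_length(dv$inter, 4L)

  # singleton species contribute only inter pairs
  sp2 <- c(a1 = "X x", a2 = "X x", b1 = "Y y", b2 = "Z z")
  dv2 <- divergence_summary(dm, sp2)
  expect_length(dv2$intra, 1L)
  expect_length(dv2$inter, 5L)

  # permuting sample order changes nothing
  perm <- c("b2", "a1", "b1", "a2")
  dvp <- divergence_summary(dm[perm, perm], sp)
  expect_equal(dvp$mean_intra, dv$mean_intra)
  expect_equal(dvp$mean_inter, dv$mean_inter)
})

test_that("locus summary reports ungapped lengths and site classes", {
  aln <- barcode_alignment(c(q1 = "ACGT-ACGT", q2 = "ACGTTACGT",
                             q3 = "ACGTTACGA", q4 = "ACG--ACGA"), "ITS")
  sp <- c(q1 = "A a", q2 = "A a", q3 = "B b", q4 = "B b")
  ls <- locus_summary(aln, sp)
  expect_equal(ls$n_sequences, 4L)
  expect_equal(ls$n_species, 2L)
  expect_equal(ls$mean_length, mean(c(8, 9, 9, 7)))
  expect_equal(ls$pct_variable, site_classes(aln)$pct_variable)
})
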