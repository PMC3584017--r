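test_that("zero divergence collapses a genus to identical sequences", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 1, species_per_genus = 3, accessions_per_species = 2,
    locus_lengths = c(L = 100L), inter_divergence = 0,
    intra_divergence = 0, seed = 1))
  expect_equal(length(unique(sd$collections$L$residues)), 1L)
})

test_that("generation is byte-identical across repeated runs of one seed", {
  spec <- synthetic_spec(n_genera = 2, species_per_genus = 2,
                         accessions_per_species = c(3, 1, 2, 2),
                         locus_lengths = c(A = 80L, B = 90L),
                         inter_divergence = 0.06, intra_divergence = 0.01,
                         indel_rate = 0.005, ambiguity_rate = 0.01, seed = 55)
  s1 <- generate_barcode_data(spec)
  s2 <- generate_barcode_data(spec)
  expect_identical(s1$collections, s2$collections)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_locus_fasta(s1$collections$A, f1)
  write_locus_fasta(s2$collections$A, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generate_barcode_data(synthetic_spec(
    n_genera = 2, species_per_genus = 2,
    accessions_per_species = c(3, 1, 2, 2),
    locus_lengths = c(A = 80L, B = 90L),
    inter_divergence = 0.06, intra_divergence = 0.01,
    indel_rate = 0.005, ambiguity_rate = 0.01, seed = 56))
  expect_false(identical(s1$collections, s3$collections))
})

test_that("invalid specs are rejected with the offending fields named", {
  expect_error(synthetic_spec(locus_lengths = c(A = 30L)), "lengths")
  expect_error(synthetic_spec(inter_divergence = 0.01,
                              intra_divergence = 0.05), "intra_divergence")
  expect_error(synthetic_spec(n_genera = 0), "n_genera")
  expect_error(synthetic_spec(locus_lengths = c(100L)), "named")
})

test_that("accession vectors create singletons and dropout thins loci", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 2, species_per_genus = 2,
    accessions_per_species = c(3, 1, 2, 1),
    locus_lengths = c(L = 60L), inter_divergence = 0.05,
    intra_divergence = 0.01, seed = 3))
  counts <- table(sd$collections$L$species)
  expect_setequal(as.integer(counts), c(3L, 1L, 2L, 1L))
  p <- partition_datasets(sd$collections$L)
  expect_equal(length(unique(p$set2$species)), 2L)

  sdd <- generate_barcode_data(synthetic_spec(
    n_genera = 3, species_per_genus = 2, accessions_per_species = 3,
    locus_lengths = c(A = 60L, B = 60L), inter_divergence = 0.05,
    intra_divergence = 0.01, dropout_rate = 0.3, seed = 8))
  nA <- nrow(sdd$collections$A); nB <- nrow(sdd$collections$B)
  expect_lt(nA + nB, 36L)  # some records dropped
  shared <- intersect(sdd$collections$A$sample_id, sdd$collections$B$sample_id)
  expect_lt(length(shared), 18L)
})

test_that("indels change lengths and ambiguity masking introduces Ns", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 1, species_per_genus = 2, accessions_per_species = 3,
    locus_lengths = c(L = 300L), inter_divergence = 0.05,
    intra_divergence = 0.01, indel_rate = 0.01, ambiguity_rate = 0.02,
    seed = 14))
  lens <- nchar(sd$collections$L$residues)
  expect_gt(length(unique(lens)), 1L)
  expect_true(any(grepl("N", sd$collections$L$residues)))
})

test_that("the truth table is consistent with direct recomputation", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 2, species_per_genus = 2, accessions_per_species = 2,
    locus_lengths = c(L = 200L), inter_divergence = 0.08,
    intra_divergence = 0.01, seed = 23))
  coll <- sd$collections$L
  dm <- distance_matrix(setNames(coll$residues, coll$sample_id))
  sp <- setNames(coll$species, coll$sample_id)
  gr <- gap_resolution(dm, sp)
  truth <- sd$truth[match(gr$summaries$species, sd$truth$species), ]
  expect_equal(gr$summaries$max_intra, truth$max_intra)
  expect_equal(gr$summaries$min_inter, truth$min_inter)
  expect_equal(gr$summaries$resolved, truth$expected_resolvable)
})

test_that("realized intra divergence recovers twice the branch rate", {
  intra <- 0.01
  rel_err <- vapply(1:15, function(seed) {
    sd <- generate_barcode_data(synthetic_spec(
      n_genera = 2, species_per_genus = 2, accessions_per_species = 3,
      locus_lengths = c(L = 600L), inter_divergence = 0.05,
      intra_divergence = intra, seed = 400 + seed))
    coll <- sd$collections$L
    dm <- distance_matrix(setNames(coll$residues, coll$sample_id))
    dv <- divergence_summary(dm, setNames(coll$species, coll$sample_id))
    dv$mean_intra
  }, numeric(1))
  expect_lt(abs(mean(rel_err) - 2 * intra) / (2 * intra), 0.2)
})

test_that("mean intra stays below mean inter under a 10x divergence ratio", {
  ok <- vapply(1:25, function(seed) {
    sd <- generate_barcode_data(synthetic_spec(
      n_genera = 2, species_per_genus = 5, accessions_per_species = 3,
      locus_lengths = c(L = 400L), inter_divergence = 0.05,
      intra_divergence = 0.005, seed = 700 + seed))
    coll <- sd$collections$L
    dm <- distance_matrix(setNames(coll$residues, coll$sample_id))
    dv <- divergence_summary(dm, setNames(coll$species, coll$sample_id))
    dv$mean_intra < dv$mean_inter
  }, logical(1))
  expect_true(all(ok))
})

test_that("generated quality reads drive the QC stage as designed", {
  set.seed(61)
  coll <- locus_collection(
    sample_id = c("s1", "s2"), species = c("X x", "Y y"), locus = "ITS",
    residues = replicate(2, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                  collapse = "")))
  clean <- generate_quality_reads(coll, "clean", overlap_fraction = 0.8)
  rep_clean <- qc_report(c(clean$forward, clean$reverse))
  expect_true(all(rep_clean$accepted))

  noisy <- generate_quality_reads(coll, "noisy_ends", overlap_fraction = 0.8)
  v <- window_trim(noisy$forward[[1]])
  n <- length(noisy$forward[[1]]$qualities)
  expect_lte(v$trimmed_span[2], n - 20)  # the QV-10 tail is gone

  # read pairs built at 60% overlap fail the strict 70% rule
  low <- generate_quality_reads(coll, "clean", overlap_fraction = 0.6)
  for (i in seq_len(nrow(coll))) {
    cov <- overlap_coverage(low$forward[[i]]$residues,
                            low$reverse[[i]]$residues)
    expect_false(cov > 0.70)
    expect_equal(as.numeric(cov), 0.6, tolerance = 0.02)
  }
})
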