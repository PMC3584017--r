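toy_dm <- function() {
  rows <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAT",
            b1 = "CCCCCCCCCC", b2 = "CCCCCCCCCG",
            c1 = "GGGGGGGGGG", c2 = "GGGGGGGGGA")
  distance_matrix(rows)
}
toy_sp <- c(a1 = "Ga a", a2 = "Ga a", b1 = "Gb b", b2 = "Gb b",
            c1 = "Gc c", c2 = "Gc c")

test_that("gap resolution applies the strict min-inter > max-intra rule", {
  gr <- gap_resolution(toy_dm(), toy_sp)
  expect_equal(gr$pct_resolved, 100)
  expect_true(all(gr$summaries$resolved))
  expect_equal(gr$summaries$max_intra, rep(0.1, 3))

  # boundary: equality is NOT resolved
  s <- data.frame(species = "S s", max_intra = 0.02, min_inter = 0.02)
  rows <- c(s1 = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
            s2 = "CAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
            t1 = "GAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  dm <- distance_matrix(rows)   # max_intra(S) = 0.02 = min_inter(S)
  sp <- c(s1 = "S s", s2 = "S s", t1 = "T t")
  gr2 <- gap_resolution(dm, sp)
  expect_equal(gr2$summaries$max_intra, gr2$summaries$min_inter)
  expect_false(gr2$summaries$resolved)
  expect_equal(gr2$pct_resolved, 0)

  expect_error(gap_resolution(dm[c("s1", "t1"), c("s1", "t1")], sp),
               "multiple accessions")
})

test_that("species with identical accessions resolve at any positive inter", {
  rows <- c(u1 = "ACGTACGT", u2 = "ACGTACGT", v1 = "ACGTACGA")
  dm <- distance_matrix(rows)
  gr <- gap_resolution(dm, c(u1 = "U u", u2 = "U u", v1 = "V v"))
  expect_equal(gr$summaries$max_intra, 0)
  expect_true(gr$summaries$resolved)
})

test_that("gap scatter flags the global barcode gap and counts points", {
  gr <- gap_resolution(toy_dm(), toy_sp)
  sc <- gap_scatter(gr)
  expect_true(attr(sc, "gap_exists"))
  expect_equal(attr(sc, "n_above"), 3L)
  # internal consistency with the resolution percentage
  expect_equal(100 * attr(sc, "n_above") / nrow(sc), gr$pct_resolved)

  sc2 <- gap_scatter(data.frame(species = c("p", "q"),
                                max_intra = c(0.01, 0.02),
                                min_inter = c(0.05, 0.02)))
  expect_false(attr(sc2, "gap_exists"))   # point on the diagonal
  expect_equal(attr(sc2, "n_above"), 1L)
})

well_separated <- function() {
  locus_collection(
    sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    species = rep(c("Ga a", "Gb b", "Gc c"), each = 2),
    locus = "ITS",
    residues = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA",
                 "TTTTCCCCGGGGAAAATTTT", "TTTTCCCCGGGGAAAATTTA",
                 "GGGGGGGGTTTTTTTTCCCC", "GGGGGGGGTTTTTTTTCCCA"))
}

test_that("best-match identification is perfect on well-separated species", {
  coll <- well_separated()
  for (sc in c("local_align", "p_distance")) {
    bm <- best_match_identify(coll, coll, scorer = sc)
    expect_equal(bm$pct_identified, 100, info = sc)
    expect_true(all(bm$results$status == "correct"), info = sc)
  }
})

test_that("ties across species are ambiguous and sink the species", {
  coll <- locus_collection(
    sample_id = c("x1", "x2", "y1", "z1", "z2"),
    species = c("X x", "X x", "Y y", "Z z", "Z z"),
    locus = "ITS",
    residues = c("AAAACCCC", "AAAACCCC", "AAAACCCC",   # y1 ties x's
                 "GGGGTTTT", "GGGGTTTA"))
  bm <- best_match_identify(coll, coll)
  st <- setNames(bm$results$status, bm$results$query_id)
  expect_equal(unname(st["x1"]), "ambiguous")  # x2 and y1 tie
  expect_equal(unname(st["y1"]), "incorrect")  # best hits are all species X
  expect_false(bm$species$identified[bm$species$species == "X x"])
  expect_true(bm$species$identified[bm$species$species == "Z z"])
})

test_that("best-match is invariant to reference shuffling and self-exclusion works", {
  coll <- well_separated()
  bm1 <- best_match_identify(coll, coll)
  shuf <- barcodeval:::subset_collection(coll, c(5, 3, 1, 6, 2, 4))
  bm2 <- best_match_identify(coll, shuf)
  expect_equal(bm1$pct_identified, bm2$pct_identified)
  expect_equal(setNames(bm2$results$status, bm2$results$query_id),
               setNames(bm1$results$status, bm1$results$query_id))

  # a singleton query species cannot match itself after self-exclusion
  single <- locus_collection(
    sample_id = c("q1", "r1", "r2"),
    species = c("Q q", "R r", "R r"),
    locus = "ITS",
    residues = c("AAAATTTT", "CCCCGGGG", "CCCCGGGG"))
  bm3 <- best_match_identify(barcodeval:::subset_collection(single, 1), single)
  expect_equal(bm3$results$status, "incorrect")
  expect_equal(bm3$pct_identified, 0)
})

test_that("all three methods agree at 100% on gap-clean synthetic data", {
  sd <- generate_barcode_data(synthetic_spec(
    n_genera = 2, species_per_genus = 2, accessions_per_species = 2,
    locus_lengths = c(L = 250L), inter_divergence = 0.1,
    intra_divergence = 0.005, seed = 13))
  coll <- sd$collections$L
  aln <- progressive_align(coll)
  sp <- setNames(coll$species, coll$sample_id)
  dm <- distance_matrix(aln)
  expect_equal(gap_resolution(dm, sp)$pct_resolved, 100)
  bs <- bootstrap_support(aln, sp, n_reps = 50, seed = 3)
  expect_equal(species_resolution_tree(bs), 100)
  expect_equal(best_match_identify(coll, coll)$pct_identified, 100)
})
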