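#' Specification for a synthetic multi-locus barcode data set
#'
#' Describes the taxonomic structure and divergence regime of a simulated
#' collection: `n_genera` genera each containing `species_per_genus`
#' species, each species holding `accessions_per_species` accessions (a
#' vector, recycled over species, creates singletons). Sequences evolve on
#' nested star phylogenies: one random root per locus, genus ancestors
#' mutated from it at `genus_divergence - inter_divergence` expected
#' substitutions per site, each species ancestor mutated from its genus
#' ancestor at `inter_divergence - intra_divergence`, and each accession
#' from its species ancestor at `intra_divergence` — so a tip diverges
#' from its genus ancestor by `inter_divergence` and from the common root
#' by `genus_divergence` in total.
#' Expected pairwise intra-specific divergence is then about
#' `2 * intra_divergence` and congeneric inter-specific divergence about
#' `2 * inter_divergence` (before multiple-hit saturation), and setting
#' `intra = inter` collapses the barcoding gap entirely: the two distance
#' distributions coincide. Substitutions are uniform over the three
#' alternative bases.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus (2 or more gives congeners
#'   for the set-3 analyses).
#' @param accessions_per_species Integer scalar or vector (recycled over
#'   species in order; use 1s to create singleton species).
#' @param locus_lengths Named integer vector of locus lengths in bases
#'   (names are locus labels); each length must be at least 50.
#' @param inter_divergence Expected substitutions/site between a tip and
#'   its genus root, in `[0, 0.75]`; congeneric species pairs differ at
#'   about twice this.
#' @param intra_divergence Within-species component: expected
#'   substitutions/site on the species-ancestor-to-accession branch; must
#'   not exceed `inter_divergence`.
#' @param genus_divergence Expected substitutions/site between a tip and
#'   the common root of the whole collection; controls how far apart
#'   genera sit (non-congeneric pairs differ at about twice this). Default
#'   `2 * inter_divergence` (capped at 0.75); must be at least
#'   `inter_divergence`.
#' @param indel_rate Per-site probability of an indel event (1-3 bases) in
#'   each accession sequence.
#' @param ambiguity_rate Per-site probability that a base is masked to `N`.
#' @param dropout_rate Per-record, per-locus probability that a sample is
#'   missing from a locus (exercises concatenation intersection).
#' @param seed Integer RNG seed; generation is fully reproducible.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genera = 5L, species_per_genus = 2L,
                           accessions_per_species = 3L,
                           locus_lengths = c(ITS = 600L, `trnH-psbA` = 450L),
                           inter_divergence = 0.05,
                           intra_divergence = 0.005,
                           genus_divergence = NULL,
                           indel_rate = 0, ambiguity_rate = 0,
                           dropout_rate = 0, seed = 1L) {
  if (is.null(genus_divergence))
    genus_divergence <- min(2 * inter_divergence, 0.75)
  spec <- list(n_genera = as.integer(n_genera),
               species_per_genus = as.integer(species_per_genus),
               accessions_per_species = as.integer(accessions_per_species),
               locus_lengths = locus_lengths,
               inter_divergence = inter_divergence,
               intra_divergence = intra_divergence,
               genus_divergence = genus_divergence,
               indel_rate = indel_rate, ambiguity_rate = ambiguity_rate,
               dropout_rate = dropout_rate, seed = as.integer(seed))
  bad <- character(0)
  if (spec$n_genera < 1L) bad <- c(bad, "n_genera must be >= 1")
  if (spec$species_per_genus < 1L) bad <- c(bad, "species_per_genus must be >= 1")
  if (any(spec$accessions_per_species < 1L))
    bad <- c(bad, "accessions_per_species must be >= 1")
  if (is.null(names(locus_lengths)) || any(!nzchar(names(locus_lengths))))
    bad <- c(bad, "locus_lengths must be named by locus")
  if (any(locus_lengths < 50L)) bad <- c(bad, "locus lengths must be >= 50")
  if (intra_divergence < 0 || inter_divergence < 0 ||
      intra_divergence > inter_divergence || inter_divergence > 0.75)
    bad <- c(bad, "need 0 <= intra_divergence <= inter_divergence <= 0.75")
  if (genus_divergence < inter_divergence || genus_divergence > 0.75)
    bad <- c(bad, "need inter_divergence <= genus_divergence <= 0.75")
  if (indel_rate < 0 || indel_rate > 0.1)
    bad <- c(bad, "indel_rate must be in [0, 0.1]")
  if (ambiguity_rate < 0 || ambiguity_rate > 0.5)
    bad <- c(bad, "ambiguity_rate must be in [0, 0.5]")
  if (dropout_rate < 0 || dropout_rate >= 1)
    bad <- c(bad, "dropout_rate must be in [0, 1)")
  if (length(bad)) stop("invalid synthetic spec: ", paste(bad, collapse = "; "))
  class(spec) <- "synthetic_spec"
  spec
}

BASES <- c("A", "C", "G", "T")

# mutate each site independently with probability `rate`, uniformly to one
# of the three alternative bases
mutate_seq <- function(base_int, rate) {
  n <- length(base_int)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    base_int[hit] <- ((base_int[hit] - 1L + shift) %% 4L) + 1L
  }
  base_int
}

apply_indels <- function(seq_chr, rate) {
  # seq_chr: character vector of single bases
  n <- length(seq_chr)
  ev <- which(runif(n) < rate)
  if (!length(ev)) return(seq_chr)
  out <- as.list(seq_chr)
  for (i in ev) {
    len <- sample.int(3L, 1L)
    if (runif(1) < 0.5) {  # insertion after site i
      out[[i]] <- c(out[[i]], sample(BASES, len, replace = TRUE))
    } else {               # deletion of up to `len` sites from i
      for (j in i:min(i + len - 1L, n)) out[[j]] <- character(0)
    }
  }
  unlist(out)
}

#' Generate a synthetic multi-locus barcode data set
#'
#' Simulates per-locus collections according to a [synthetic_spec()] and
#' returns, alongside them, a truth table of the realized per-species
#' divergence structure (computed from the substitution-only sequences,
#' before indels and ambiguity masking, where all sequences share the locus
#' length and p-distances need no alignment).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_data`: `collections` (named list of
#'   [locus_collection()], one per locus), `truth` (data frame per locus x
#'   species: realized `max_intra`, `min_inter`, `expected_resolvable`),
#'   and `spec`.
#' @examples
#' sd <- generate_barcode_data(synthetic_spec(seed = 42))
#' sd$collections$ITS
#' @export
generate_barcode_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_sp <- spec$n_genera * spec$species_per_genus
  acc <- rep_len(spec$accessions_per_species, n_sp)
  genus_names <- sprintf("Genus%02d", seq_len(spec$n_genera))
  species <- character(0)
  genus_of_sp <- character(0)
  for (g in seq_len(spec$n_genera)) {
    for (s in seq_len(spec$species_per_genus)) {
      species <- c(species, sprintf("%s species%02d", genus_names[g], s))
      genus_of_sp <- c(genus_of_sp, genus_names[g])
    }
  }
  sample_species <- rep(species, acc)
  sample_id <- unlist(lapply(seq_len(n_sp), function(i)
    sprintf("%s_a%d", gsub(" ", "_", species[i]), seq_len(acc[i]))))
  collections <- list()
  truth <- list()
  for (locus in names(spec$locus_lengths)) {
    L <- spec$locus_lengths[[locus]]
    clean <- character(length(sample_id))
    k <- 0L
    global_root <- sample.int(4L, L, replace = TRUE)
    for (g in seq_len(spec$n_genera)) {
      # genus branch carries the across-genus component of tip divergence
      root <- mutate_seq(global_root,
                         spec$genus_divergence - spec$inter_divergence)
      for (s in seq_len(spec$species_per_genus)) {
        sp_idx <- (g - 1L) * spec$species_per_genus + s
        # species branch carries the between-species component so that a
        # tip diverges from the genus root by inter_divergence in total;
        # with intra == inter the species branch vanishes and the intra-
        # and inter-specific distance distributions coincide (no gap)
        anc <- mutate_seq(root, spec$inter_divergence - spec$intra_divergence)
        for (a in seq_len(acc[sp_idx])) {
          k <- k + 1L
          clean[k] <- paste(BASES[mutate_seq(anc, spec$intra_divergence)],
                            collapse = "")
        }
      }
    }
    # truth from substitution-only sequences
    dm <- pdist_matrix_cpp(clean)
    dimnames(dm) <- list(sample_id, sample_id)
    tr <- lapply(species, function(s) {
      in_s <- sample_species == s
      if (sum(in_s) >= 2) {
        intra <- dm[in_s, in_s][upper.tri(diag(sum(in_s)))]
        max_intra <- max(intra)
      } else max_intra <- NA_real_
      others <- dm[in_s, !in_s, drop = FALSE]
      min_inter <- if (length(others)) min(others) else NA_real_
      data.frame(locus = locus, species = s, n_accessions = sum(in_s),
                 max_intra = max_intra, min_inter = min_inter,
                 expected_resolvable = !is.na(max_intra) && !is.na(min_inter) &&
                   min_inter > max_intra,
                 stringsAsFactors = FALSE)
    })
    truth[[locus]] <- do.call(rbind, tr)
    # decorate: ambiguity masking, then indels
    final <- vapply(clean, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (spec$ambiguity_rate > 0) {
        mask <- runif(length(ch)) < spec$ambiguity_rate
        ch[mask] <- "N"
      }
      if (spec$indel_rate > 0) ch <- apply_indels(ch, spec$indel_rate)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    keep <- if (spec$dropout_rate > 0)
      runif(length(sample_id)) >= spec$dropout_rate else
      rep(TRUE, length(sample_id))
    collections[[locus]] <- locus_collection(
      sample_id = sample_id[keep], species = sample_species[keep],
      locus = locus, residues = final[keep])
  }
  structure(list(collections = collections,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 spec = spec),
            class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat(sprintf("Synthetic barcode data: %d loci, %d species, seed %d\n",
              length(x$collections),
              length(unique(x$truth$species)), x$spec$seed))
  for (coll in x$collections) print(coll)
  invisible(x)
}

#' Generate paired quality reads for a collection
#'
#' Produces forward/reverse Sanger-style read pairs for every record of a
#' collection, to exercise the quality-control stage: the forward read
#' covers the 5' portion and the reverse read (reverse-complemented) the 3'
#' portion, overlapping by `overlap_fraction` of the template. The
#' `"clean"` profile gives uniformly high qualities; `"noisy_ends"` sets
#' the 3'-terminal `noisy_len` bases of each read to `qv_low`, which the
#' windowed trimming rule should remove.
#'
#' @param coll A [locus_collection()].
#' @param profile `"clean"` or `"noisy_ends"`.
#' @param overlap_fraction Fraction of the template covered by both reads.
#' @param qv_high,qv_low High/low Phred values (defaults 40 and 10).
#' @param noisy_len Length of the low-quality 3' tail (default 25).
#' @param seed Integer seed (reserved for future stochastic profiles;
#'   generation is currently deterministic given the collection).
#' @return A list with `forward` and `reverse`, each a list of quality
#'   reads (`read_id`, `residues`, `qualities`, `direction`).
#' @export
generate_quality_reads <- function(coll, profile = c("clean", "noisy_ends"),
                                   overlap_fraction = 0.8, qv_high = 40L,
                                   qv_low = 10L, noisy_len = 25L, seed = 1L) {
  profile <- match.arg(profile)
  set.seed(seed)
  fwd <- list()
  rev <- list()
  for (i in seq_len(nrow(coll))) {
    tmpl <- gsub("-", "", coll$residues[i], fixed = TRUE)
    L <- nchar(tmpl)
    rl <- ceiling(L * (1 + overlap_fraction) / 2)
    rl <- min(max(rl, 1L), L)
    f_seq <- substr(tmpl, 1L, rl)
    r_seq <- revcomp(substr(tmpl, L - rl + 1L, L))
    mk_q <- function(n) {
      q <- rep(as.integer(qv_high), n)
      if (profile == "noisy_ends" && n > noisy_len)
        q[(n - noisy_len + 1L):n] <- as.integer(qv_low)
      q
    }
    fwd[[i]] <- list(read_id = paste0(coll$sample_id[i], "_F"),
                     residues = f_seq, qualities = mk_q(nchar(f_seq)),
                     direction = "forward")
    rev[[i]] <- list(read_id = paste0(coll$sample_id[i], "_R"),
                     residues = r_seq, qualities = mk_q(nchar(r_seq)),
                     direction = "reverse")
  }
  list(forward = fwd, reverse = rev)
}
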