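#' Build a locus collection of labelled barcode sequences
#'
#' A locus collection holds one sequence per specimen for a single barcode
#' locus, together with its species label. It is the basic input unit of the
#' evaluation pipeline: distance matrices, discrimination methods and summary
#' statistics all operate on locus collections (or on alignments derived from
#' them).
#'
#' Residues are canonicalized on construction: upper-cased, with `U`
#' converted to `T`. Only IUPAC nucleotide codes and the gap character `-`
#' are accepted. The genus is always the first whitespace-delimited token of
#' the species binomial.
#'
#' @param sample_id Character vector of unique specimen identifiers.
#' @param species Character vector of species binomials ("Genus epithet").
#' @param locus Single locus label (e.g. `"ITS"`, `"rbcL"`, `"trnH-psbA"`).
#' @param residues Character vector of DNA sequences, one per specimen.
#' @param source Character vector (or scalar) in `{"study", "external"}`;
#'   externally supplemented records are flagged but analysed identically.
#' @return An object of class `locus_collection`: a data frame with columns
#'   `sample_id`, `species`, `genus`, `locus`, `source`, `residues` and a
#'   `locus` attribute.
#' @examples
#' coll <- locus_collection(
#'   sample_id = c("s1", "s2", "s3"),
#'   species   = c("Ficus religiosa", "Ficus religiosa", "Shorea robusta"),
#'   locus     = "ITS",
#'   residues  = c("ACGTACGT", "ACGTACGA", "ACGTTTTT"))
#' coll
#' @export
locus_collection <- function(sample_id, species, locus, residues,
                             source = "study") {
  sample_id <- as.character(sample_id)
  species <- as.character(species)
  residues <- toupper(as.character(residues))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  if (length(locus) != 1L) stop("'locus' must be a single label")
  n <- length(sample_id)
  if (length(species) != n || length(residues) != n)
    stop("sample_id, species and residues must have equal length")
  source <- rep_len(as.character(source), n)
  if (!all(source %in% c("study", "external")))
    stop("source must be 'study' or 'external'")
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample_id in collection: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(residues)))
    stop("empty residues for: ",
         paste(sample_id[!nzchar(residues)], collapse = ", "))
  bad_chr <- vapply(strsplit(residues, ""), function(ch)
    any(!ch %in% IUPAC_CODES), logical(1))
  if (any(bad_chr))
    stop("non-IUPAC characters in: ",
         paste(sample_id[bad_chr], collapse = ", "))
  genus <- vapply(strsplit(species, "\\s+"), `[`, character(1), 1L)
  out <- data.frame(sample_id = sample_id, species = species, genus = genus,
                    locus = rep_len(locus, n), source = source,
                    residues = residues, stringsAsFactors = FALSE)
  attr(out, "locus") <- locus
  class(out) <- c("locus_collection", "data.frame")
  out
}

#' @export
print.locus_collection <- function(x, ...) {
  cat(sprintf("Locus collection: %s\n", attr(x, "locus")))
  cat(sprintf("  %d sequences, %d species, %d genera\n",
              nrow(x), length(unique(x$species)), length(unique(x$genus))))
  if (nrow(x)) {
    len <- nchar(gsub("-", "", x$residues))
    cat(sprintf("  ungapped length: %.1f +/- %.1f (range %d-%d)\n",
                mean(len), if (nrow(x) > 1) sd(len) else 0,
                min(len), max(len)))
  }
  invisible(x)
}

subset_collection <- function(coll, keep) {
  out <- coll[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "locus") <- attr(coll, "locus")
  class(out) <- c("locus_collection", "data.frame")
  out
}

#' Read a locus collection from FASTA plus a metadata table
#'
#' FASTA headers (the first whitespace-delimited token of each `>` line) are
#' matched to the `sample_id` column of a tab-delimited metadata table with
#' columns `sample_id`, `species`, `locus` and optionally `source`. A header
#' without a metadata row, or a duplicated id, is a hard error.
#'
#' @param fasta Path to a FASTA file (wrapped or unwrapped).
#' @param metadata Path to the metadata TSV (header row required), or a
#'   data frame with the same columns.
#' @param locus Locus label; defaults to the unique `locus` value of the
#'   matched metadata rows.
#' @return A [locus_collection()].
#' @export
read_locus_fasta <- function(fasta, metadata, locus = NULL) {
  dna <- ape::read.FASTA(fasta)
  ids <- names(dna)
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  meta <- if (is.data.frame(metadata)) metadata else
    read.delim(metadata, stringsAsFactors = FALSE)
  need <- c("sample_id", "species")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss))
    stop("FASTA ids missing from metadata: ", paste(miss, collapse = ", "))
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (is.null(locus))
    locus <- if ("locus" %in% names(m)) unique(m$locus)[1] else "locus"
  src <- if ("source" %in% names(m)) m$source else "study"
  locus_collection(sample_id = ids, species = m$species, locus = locus,
                   residues = seqs, source = src)
}

#' Write a locus collection as FASTA plus metadata TSV
#'
#' The written pair round-trips exactly through [read_locus_fasta()]:
#' sample ids, species labels and residues are preserved.
#'
#' @param coll A [locus_collection()].
#' @param fasta Output FASTA path.
#' @param metadata Output metadata TSV path (optional).
#' @return Invisibly, `coll`.
#' @export
write_locus_fasta <- function(coll, fasta, metadata = NULL) {
  dna <- ape::as.DNAbin(setNames(strsplit(tolower(coll$residues), ""),
                                 coll$sample_id))
  ape::write.FASTA(dna, fasta)
  if (!is.null(metadata)) {
    write.table(coll[, c("sample_id", "species", "genus", "locus", "source")],
                metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(coll)
}

#' Partition a collection into the three analysis data sets
#'
#' Barcoding surveys evaluate discrimination on three nested sample sets:
#' set 1 contains every sample; set 2 the species represented by two or more
#' accessions (needed for any intra-specific quantity); set 3 the congeneric
#' subset of set 2 — species that both have multiple accessions and share
#' their genus with another qualifying species, giving the hardest, most
#' closely related comparisons.
#'
#' @param coll A [locus_collection()].
#' @param congener_rule `"multi"` (default): a set-3 species must share its
#'   genus with at least one *other multi-accession* species. `"any"`: any
#'   congener in the full collection qualifies it (its own accession count
#'   must still be >= 2).
#' @return A list of class `dataset_partition` with elements `set1`, `set2`,
#'   `set3`, each a [locus_collection()].
#' @examples
#' coll <- locus_collection(
#'   sample_id = c("a1", "a2", "b1", "c1", "c2"),
#'   species = c("Ficus religiosa", "Ficus religiosa", "Ficus benghalensis",
#'               "Shorea robusta", "Shorea robusta"),
#'   locus = "ITS",
#'   residues = rep("ACGT", 5))
#' p <- partition_datasets(coll)
#' nrow(p$set2)  # 4: both multi-accession species
#' nrow(p$set3)  # 0: no genus holds two multi-accession species
#' @export
partition_datasets <- function(coll, congener_rule = c("multi", "any")) {
  congener_rule <- match.arg(congener_rule)
  counts <- table(coll$species)
  multi <- names(counts)[counts >= 2]
  in2 <- coll$species %in% multi
  sp_genus <- unique(coll[, c("species", "genus")])
  if (congener_rule == "multi") {
    g_multi <- sp_genus[sp_genus$species %in% multi, , drop = FALSE]
    gtab <- table(g_multi$genus)
    good_gen <- names(gtab)[gtab >= 2]
    set3_sp <- g_multi$species[g_multi$genus %in% good_gen]
  } else {
    gtab <- table(sp_genus$genus)
    good_gen <- names(gtab)[gtab >= 2]
    set3_sp <- intersect(multi, sp_genus$species[sp_genus$genus %in% good_gen])
  }
  out <- list(set1 = coll,
              set2 = subset_collection(coll, in2),
              set3 = subset_collection(coll, coll$species %in% set3_sp))
  class(out) <- "dataset_partition"
  out
}

#' @export
print.dataset_partition <- function(x, ...) {
  for (s in names(x)) {
    cat(sprintf("%s: %d sequences, %d species\n", s, nrow(x[[s]]),
                length(unique(x[[s]]$species))))
  }
  invisible(x)
}
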