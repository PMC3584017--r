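#' Construct an alignment object
#'
#' @param rows Named character vector of equal-length gapped rows (names are
#'   sample ids).
#' @param label Locus or combination label.
#' @param partitions Optional data frame (`locus`, `start`, `end`; 0-based
#'   half-open) recording locus boundaries in a concatenated alignment.
#' @return An object of class `barcode_alignment`.
#' @export
barcode_alignment <- function(rows, label = "locus", partitions = NULL) {
  rows <- toupper(rows)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must be uniquely named by sample_id")
  if (length(unique(nchar(rows))) != 1L)
    stop("all rows must have equal length")
  structure(list(label = label, ids = names(rows), rows = rows,
                 length = nchar(rows[[1]]), partitions = partitions),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("Alignment '%s': %d rows x %d columns\n",
              x$label, length(x$rows), x$length))
  if (!is.null(x$partitions)) {
    cat("  partitions:\n")
    print(x$partitions)
  }
  invisible(x)
}

#' @export
as.matrix.barcode_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), ""))
  rownames(m) <- x$ids
  m
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch-Gotoh alignment of two DNA strings. A gap of length L
#' costs `gap_open + (L - 1) * gap_extend`. Ties in the traceback are broken
#' deterministically: a match/mismatch step is preferred over a gap, and a
#' gap in the first sequence over a gap in the second.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   +1, -1, -4, -1).
#' @return A list with `a`, `b` (gapped strings of equal length) and
#'   `score`.
#' @examples
#' pairwise_align("ACGT", "AGT", gap_open = -2, gap_extend = -2)
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap_open, gap_extend)
}

# distance = 1 - shared k-mer fraction (shared distinct k-mers over the
# smaller distinct-k-mer set); alignment-free guide-tree metric
kmer_distance <- function(seqs, k = 6L) {
  sets <- lapply(seqs, function(s) {
    s <- gsub("-", "", s)
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1L)
    }
  }
  d
}

apply_gaps <- function(rows, is_gap) {
  # insert gap columns into each row of a profile at positions where is_gap
  out_len <- length(is_gap)
  chars <- strsplit(unname(rows), "")
  new <- vapply(chars, function(ch) {
    v <- character(out_len)
    v[is_gap] <- "-"
    v[!is_gap] <- ch
    paste(v, collapse = "")
  }, character(1))
  names(new) <- names(rows)
  new
}

#' Progressive multiple sequence alignment
#'
#' A deterministic progressive aligner standing in for external tools such
#' as ClustalW: a guide tree is built by neighbor joining on an
#' alignment-free 6-mer distance, and profiles are merged in post-order
#' with affine-gap profile-profile dynamic programming. Already-aligned
#' input (rows of equal length containing `-`) can be passed through
#' unchanged with `passthrough = TRUE`, so that externally computed
#' alignments are usable everywhere downstream.
#'
#' @param coll A [locus_collection()], or a named character vector of
#'   sequences.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param kmer Guide-tree k-mer size (default 6).
#' @param passthrough If `TRUE` and the input rows already contain gap
#'   characters and share one length, they are returned as-is.
#' @return A [barcode_alignment()].
#' @export
progressive_align <- function(coll, match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1, kmer = 6L,
                              passthrough = FALSE) {
  if (inherits(coll, "locus_collection")) {
    seqs <- setNames(coll$residues, coll$sample_id)
    label <- attr(coll, "locus")
  } else {
    seqs <- coll
    label <- "locus"
  }
  if (is.null(names(seqs))) stop("sequences must be named")
  if (passthrough && any(grepl("-", seqs, fixed = TRUE))) {
    if (length(unique(nchar(seqs))) != 1L)
      stop("passthrough requires pre-aligned rows of equal length")
    return(barcode_alignment(seqs, label = label))
  }
  seqs <- setNames(gsub("-", "", toupper(seqs), fixed = TRUE), names(seqs))
  n <- length(seqs)
  if (n == 1L) return(barcode_alignment(seqs, label = label))
  merge_profiles <- function(A, B) {
    al <- profile_align_cpp(unname(A), unname(B), match, mismatch,
                            gap_open, gap_extend)
    c(apply_gaps(A, al$gapA), apply_gaps(B, al$gapB))
  }
  if (n == 2L) {
    aligned <- merge_profiles(seqs[1], seqs[2])
    return(barcode_alignment(aligned[names(seqs)], label = label))
  }
  d <- kmer_distance(seqs, k = kmer)
  dimnames(d) <- list(names(seqs), names(seqs))
  guide <- ape::nj(as.dist(d))
  guide <- phangorn::midpoint(guide)
  guide <- ape::multi2di(guide)
  # post-order merge over the rooted guide tree
  align_node <- function(node) {
    ntip <- length(guide$tip.label)
    if (node <= ntip) {
      tip <- guide$tip.label[node]
      return(setNames(seqs[tip], tip))
    }
    children <- guide$edge[guide$edge[, 1] == node, 2]
    prof <- align_node(children[1])
    for (ch in children[-1]) prof <- merge_profiles(prof, align_node(ch))
    prof
  }
  root <- length(guide$tip.label) + 1L
  aligned <- align_node(root)
  barcode_alignment(aligned[names(seqs)], label = label)
}

#' Concatenate per-locus alignments over shared samples
#'
#' Multi-locus barcode combinations are analysed on the samples sequenced
#' at every component locus: rows are restricted to the intersection of
#' sample ids and concatenated left to right. Locus boundaries are recorded
#' in the `partitions` table of the result.
#'
#' @param alignments A list of two or more [barcode_alignment()] objects.
#' @return A [barcode_alignment()] whose label joins the input labels with
#'   `+` and whose length is the sum of input lengths.
#' @export
concatenate_alignments <- function(alignments) {
  if (length(alignments) < 2L) stop("need at least two alignments")
  ids <- Reduce(intersect, lapply(alignments, function(a) a$ids))
  if (length(ids) == 0L)
    stop("no samples shared across all alignments")
  pieces <- lapply(alignments, function(a) a$rows[ids])
  rows <- setNames(do.call(paste0, pieces), ids)
  lens <- vapply(alignments, function(a) a$length, numeric(1))
  ends <- cumsum(lens)
  parts <- data.frame(locus = vapply(alignments, function(a) a$label, character(1)),
                      start = c(0, ends[-length(ends)]), end = ends,
                      stringsAsFactors = FALSE)
  barcode_alignment(rows,
                    label = paste(parts$locus, collapse = "+"),
                    partitions = parts)
}

#' Restrict an alignment to a subset of samples
#'
#' @param aln A [barcode_alignment()].
#' @param ids Sample ids to keep (order preserved from the alignment).
#' @return A [barcode_alignment()].
#' @export
subset_alignment <- function(aln, ids) {
  keep <- aln$ids[aln$ids %in% ids]
  if (length(keep) == 0L) stop("no matching ids in alignment")
  barcode_alignment(aln$rows[keep], label = aln$label,
                    partitions = aln$partitions)
}

#' Write an alignment as gapped FASTA (with optional partition table)
#'
#' @param aln A [barcode_alignment()].
#' @param fasta Output FASTA path.
#' @param partitions Optional path for a TSV of locus boundaries.
#' @return Invisibly, `aln`.
#' @export
write_alignment <- function(aln, fasta, partitions = NULL) {
  dna <- ape::as.DNAbin(setNames(strsplit(tolower(aln$rows), ""), aln$ids))
  ape::write.FASTA(dna, fasta)
  if (!is.null(partitions) && !is.null(aln$partitions))
    write.table(aln$partitions, partitions, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(aln)
}
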