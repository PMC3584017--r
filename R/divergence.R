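#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of differing sites among compared sites, uncorrected for
#' multiple hits, under pairwise deletion: by default only columns where
#' *both* rows carry an unambiguous base (A/C/G/T) are compared; gaps and
#' ambiguity codes are treated as missing. With
#' `ambiguity = "partial-match"`, ambiguity codes are compared too and count
#' as a match whenever their IUPAC sets intersect.
#'
#' @param a,b Gapped rows of equal length.
#' @param ambiguity `"missing"` (default) or `"partial-match"`.
#' @return The p-distance in `[0, 1]`, or `NA` if no site is comparable.
#' @examples
#' p_distance("ACGT", "ACGA")   # 0.25
#' p_distance("AC-T", "AGGT")   # 1/3: gapped column excluded
#' @export
p_distance <- function(a, b, ambiguity = c("missing", "partial-match")) {
  ambiguity <- match.arg(ambiguity)
  if (nchar(a) != nchar(b)) stop("rows must have equal length")
  pdist_pair_cpp(toupper(a), toupper(b), ambiguity == "partial-match")
}

#' Pairwise p-distance matrix of an alignment
#'
#' Computes all pairwise p-distances under pairwise deletion (see
#' [p_distance()]). Pairs sharing no comparable site get `NA` and a single
#' warning reports how many entries are missing.
#'
#' @param aln A [barcode_alignment()] (or named character vector of
#'   equal-length rows).
#' @param ambiguity Passed to [p_distance()].
#' @return A symmetric numeric matrix with zero diagonal, dimnames the
#'   sample ids, of class `c("pdist", "matrix")`.
#' @export
distance_matrix <- function(aln, ambiguity = c("missing", "partial-match")) {
  ambiguity <- match.arg(ambiguity)
  rows <- if (inherits(aln, "barcode_alignment")) aln$rows else toupper(aln)
  if (length(rows) < 2L) stop("need at least two rows")
  d <- pdist_matrix_cpp(unname(rows), ambiguity == "partial-match")
  dimnames(d) <- list(names(rows), names(rows))
  n_missing <- sum(is.na(d)) / 2
  if (n_missing > 0)
    warning(sprintf("%d sequence pair(s) share no comparable site", n_missing))
  class(d) <- c("pdist", class(d))
  d
}

#' Variable and parsimony-informative site percentages
#'
#' A column is *variable* when at least two distinct unambiguous bases
#' occur in it, and *parsimony-informative* when at least two distinct
#' bases each occur in at least two rows. Gaps and ambiguity codes are
#' ignored within a column. Percentages are over all aligned columns.
#'
#' @param aln A [barcode_alignment()] or named character vector of rows.
#' @return A list with `pct_variable`, `pct_pic`, `n_columns`,
#'   `n_variable`, `n_pic`.
#' @export
site_classes <- function(aln) {
  m <- if (inherits(aln, "barcode_alignment")) as.matrix(aln) else
    do.call(rbind, strsplit(toupper(aln), ""))
  nc <- ncol(m)
  counts <- vapply(c("A", "C", "G", "T"), function(b) colSums(m == b),
                   numeric(nc))
  if (nc == 1L) counts <- matrix(counts, nrow = 1L)
  n_var <- sum(rowSums(counts > 0) >= 2)
  n_pic <- sum(rowSums(counts >= 2) >= 2)
  list(pct_variable = 100 * n_var / nc, pct_pic = 100 * n_pic / nc,
       n_columns = nc, n_variable = n_var, n_pic = n_pic)
}

#' Per-locus summary statistics
#'
#' The descriptive statistics reported per locus and data set in barcoding
#' surveys: number of sequences and species, mean (and SD) ungapped
#' sequence length, and the percentages of variable and
#' parsimony-informative sites in the alignment.
#'
#' @param aln A [barcode_alignment()].
#' @param species_of Named character vector mapping sample id to species.
#' @return A one-row data frame.
#' @export
locus_summary <- function(aln, species_of) {
  lens <- nchar(gsub("-", "", aln$rows, fixed = TRUE))
  sc <- site_classes(aln)
  sp <- species_of[aln$ids]
  data.frame(locus = aln$label,
             n_sequences = length(aln$ids),
             n_species = length(unique(sp)),
             mean_length = mean(lens),
             sd_length = if (length(lens) > 1) sd(lens) else 0,
             pct_variable = sc$pct_variable,
             pct_pic = sc$pct_pic,
             stringsAsFactors = FALSE)
}

# split a distance matrix into within- and between-species pair lists
split_pairs <- function(dm, species_of) {
  ids <- rownames(dm)
  sp <- species_of[ids]
  if (any(is.na(sp))) stop("species_of is missing some sample ids")
  ut <- upper.tri(dm)
  same <- outer(sp, sp, "==")
  list(intra = dm[ut & same], inter = dm[ut & !same])
}

#' Intra- and inter-specific divergence summary
#'
#' Splits all pairwise distances into within-species and between-species
#' pairs and reports their means. By default the means are simple averages
#' over pairs; `average = "species"` instead averages the per-species mean
#' intra-specific distances (and, for inter, the per-species means of
#' distances to all other species).
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param species_of Named character vector mapping sample id to species.
#' @param average `"pairs"` (default) or `"species"`.
#' @return A list of class `divergence_summary` with `mean_intra`,
#'   `mean_inter`, `intra` and `inter` (the pair value vectors), and
#'   `per_species` (data frame of per-species mean intra/inter).
#' @export
divergence_summary <- function(dm, species_of, average = c("pairs", "species")) {
  average <- match.arg(average)
  ids <- rownames(dm)
  sp <- species_of[ids]
  if (length(unique(sp)) < 2L) stop("need at least two species")
  pairs <- split_pairs(dm, species_of)
  per_sp <- lapply(unique(sp), function(s) {
    in_s <- sp == s
    intra <- if (sum(in_s) >= 2) {
      sub <- dm[in_s, in_s, drop = FALSE]
      mean(sub[upper.tri(sub)], na.rm = TRUE)
    } else NA_real_
    inter <- mean(dm[in_s, !in_s], na.rm = TRUE)
    data.frame(species = s, mean_intra = intra, mean_inter = inter,
               stringsAsFactors = FALSE)
  })
  per_sp <- do.call(rbind, per_sp)
  if (average == "pairs") {
    mean_intra <- if (length(pairs$intra)) mean(pairs$intra, na.rm = TRUE) else NA_real_
    mean_inter <- mean(pairs$inter, na.rm = TRUE)
  } else {
    mean_intra <- mean(per_sp$mean_intra, na.rm = TRUE)
    mean_inter <- mean(per_sp$mean_inter, na.rm = TRUE)
  }
  if (is.nan(mean_intra)) mean_intra <- NA_real_
  structure(list(mean_intra = mean_intra, mean_inter = mean_inter,
                 intra = pairs$intra, inter = pairs$inter,
                 per_species = per_sp, average = average),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Divergence summary (%s-weighted):\n", x$average))
  cat(sprintf("  mean intra-specific p-distance: %s (%d pairs)\n",
              format(x$mean_intra, digits = 4), length(x$intra)))
  cat(sprintf("  mean inter-specific p-distance: %s (%d pairs)\n",
              format(x$mean_inter, digits = 4), length(x$inter)))
  invisible(x)
}

#' Write a distance matrix as PHYLIP square format or long TSV
#'
#' @param dm Distance matrix.
#' @param path Output path.
#' @param format `"phylip"` (square matrix) or `"tsv"` (long format with
#'   columns `id1`, `id2`, `distance`).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm)), con)
    for (i in seq_len(nrow(dm))) {
      writeLines(paste(formatC(rownames(dm)[i], width = -10),
                       paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
    }
  } else {
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    long <- data.frame(id1 = rownames(dm)[idx[, 1]],
                       id2 = colnames(dm)[idx[, 2]],
                       distance = dm[idx], stringsAsFactors = FALSE)
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
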