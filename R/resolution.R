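#' Barcoding-gap species resolution
#'
#' For every species with two or more accessions, the maximum
#' intra-specific p-distance is compared with the minimum distance from any
#' of its accessions to any sample of another species. A species is
#' resolved when its minimum inter-specific distance is *strictly* greater
#' than its maximum intra-specific distance; the resolution percentage is
#' taken over multi-accession species only.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param species_of Named character vector mapping sample id to species.
#' @return A list of class `gap_resolution` with `summaries` (data frame:
#'   `species`, `n_accessions`, `max_intra`, `min_inter`, `resolved`) and
#'   `pct_resolved`.
#' @examples
#' rows <- c(a1 = "AAAA", a2 = "AAAT", b1 = "CCCC", b2 = "CCCG")
#' dm <- distance_matrix(rows)
#' sp <- c(a1 = "X x", a2 = "X x", b1 = "Y y", b2 = "Y y")
#' gap_resolution(dm, sp)$pct_resolved  # 100
#' @export
gap_resolution <- function(dm, species_of) {
  ids <- rownames(dm)
  sp <- species_of[ids]
  if (any(is.na(sp))) stop("species_of is missing some sample ids")
  counts <- table(sp)
  multi <- names(counts)[counts >= 2]
  if (length(multi) == 0L) stop("no species with multiple accessions")
  rows <- lapply(multi, function(s) {
    in_s <- sp == s
    intra <- dm[in_s, in_s, drop = FALSE][upper.tri(diag(sum(in_s)))]
    inter <- dm[in_s, !in_s, drop = FALSE]
    max_intra <- if (all(is.na(intra))) NA_real_ else max(intra, na.rm = TRUE)
    min_inter <- if (all(is.na(inter))) NA_real_ else min(inter, na.rm = TRUE)
    resolved <- !is.na(max_intra) && !is.na(min_inter) && min_inter > max_intra
    data.frame(species = s, n_accessions = sum(in_s),
               max_intra = max_intra, min_inter = min_inter,
               resolved = resolved, stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, rows)
  structure(list(summaries = summaries,
                 pct_resolved = 100 * sum(summaries$resolved) / nrow(summaries)),
            class = "gap_resolution")
}

#' @export
print.gap_resolution <- function(x, ...) {
  cat(sprintf("Barcoding gap: %d/%d species resolved (%.1f%%)\n",
              sum(x$summaries$resolved), nrow(x$summaries), x$pct_resolved))
  invisible(x)
}

#' Gap scatter table (min inter vs max intra per species)
#'
#' One point per multi-accession species, as plotted in barcode-gap
#' scatter figures: x = maximum intra-specific distance, y = minimum
#' inter-specific distance. The data set shows a global barcode gap only
#' when every point lies strictly above the y = x diagonal.
#'
#' @param x A `gap_resolution` object or its `summaries` data frame.
#' @return A data frame (`species`, `max_intra`, `min_inter`, `above`),
#'   with attributes `gap_exists` (all points strictly above the diagonal)
#'   and `n_above`.
#' @export
gap_scatter <- function(x) {
  s <- if (inherits(x, "gap_resolution")) x$summaries else x
  if (NROW(s) == 0L) stop("no species summaries")
  out <- data.frame(species = s$species, max_intra = s$max_intra,
                    min_inter = s$min_inter,
                    above = !is.na(s$min_inter) & !is.na(s$max_intra) &
                      s$min_inter > s$max_intra,
                    stringsAsFactors = FALSE)
  attr(out, "gap_exists") <- all(out$above)
  attr(out, "n_above") <- sum(out$above)
  out
}

#' Leave-one-out best-match identification against a self database
#'
#' Emulates the standalone-BLAST protocol of barcoding surveys: a reference
#' database is built from the full collection (data set 1) and every query
#' sequence is scored against all reference records except itself
#' (self-hits are excluded by sample id, so identical sequences from other
#' specimens still count). A query is `correct` when all top-scoring hits
#' belong to its own species, `ambiguous` when the top score is tied across
#' its own and other species, and `incorrect` otherwise. A species counts
#' as identified when its queries succeed under `species_rule` (default:
#' all of them must be correct); the percentage is over query species.
#'
#' @param queries A [locus_collection()] of query records (each present in
#'   the reference).
#' @param reference A [locus_collection()] forming the self database.
#' @param scorer `"local_align"` (default; affine Smith-Waterman score,
#'   higher is better) or `"p_distance"` (p-distance over a global pairwise
#'   alignment, lower is better).
#' @param species_rule `"all"` (default), `"any"` or `"majority"`:
#'   aggregation of query outcomes into species identification.
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return A list of class `best_match` with `results` (per query:
#'   `query_id`, `species`, `best_ids`, `best_species`, `status`),
#'   `species` (per species: `identified`), and `pct_identified`.
#' @export
best_match_identify <- function(queries, reference,
                                scorer = c("local_align", "p_distance"),
                                species_rule = c("all", "any", "majority"),
                                match = 1, mismatch = -1,
                                gap_open = -4, gap_extend = -1) {
  scorer <- match.arg(scorer)
  species_rule <- match.arg(species_rule)
  if (nrow(reference) < 2L) stop("reference needs at least two records")
  score_one <- function(q, r) {
    if (scorer == "local_align") {
      sw_align_cpp(q, r, match, mismatch, gap_open, gap_extend)$score
    } else {
      al <- nw_align_cpp(q, r, match, mismatch, gap_open, gap_extend)
      d <- pdist_pair_cpp(al$a, al$b)
      if (is.na(d)) 1 else d
    }
  }
  better <- if (scorer == "local_align") `>` else `<`
  res <- lapply(seq_len(nrow(queries)), function(i) {
    qid <- queries$sample_id[i]
    qsp <- queries$species[i]
    refs <- reference[reference$sample_id != qid, , drop = FALSE]
    if (nrow(refs) == 0L)
      return(data.frame(query_id = qid, species = qsp, best_ids = "",
                        best_species = "", status = "incorrect",
                        stringsAsFactors = FALSE))
    sc <- vapply(refs$residues, function(r) score_one(queries$residues[i], r),
                 numeric(1))
    best <- if (scorer == "local_align") max(sc) else min(sc)
    top <- which(!better(best, sc) & !better(sc, best))
    hit_sp <- unique(refs$species[top])
    status <- if (all(hit_sp == qsp)) "correct"
      else if (qsp %in% hit_sp) "ambiguous" else "incorrect"
    data.frame(query_id = qid, species = qsp,
               best_ids = paste(refs$sample_id[top], collapse = ","),
               best_species = paste(hit_sp, collapse = ","),
               status = status, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  agg <- tapply(results$status == "correct", results$species, function(ok) {
    switch(species_rule,
           all = all(ok),
           any = any(ok),
           majority = mean(ok) > 0.5)
  })
  species <- data.frame(species = names(agg), identified = as.logical(agg),
                        stringsAsFactors = FALSE)
  structure(list(results = results, species = species,
                 pct_identified = 100 * mean(species$identified)),
            class = "best_match")
}

#' @export
print.best_match <- function(x, ...) {
  cat(sprintf("Best-match identification: %d/%d species (%.1f%%)\n",
              sum(x$species$identified), nrow(x$species), x$pct_identified))
  tab <- table(x$results$status)
  cat("  query outcomes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
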