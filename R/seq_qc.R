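#' Windowed quality trimming of a Sanger read
#'
#' Applies the terminal-segment trimming rule used for capillary barcode
#' reads: starting from each end of the read, successive `window`-base
#' segments are removed while a segment contains at least `bad_per_window`
#' bases with quality value (QV) below `qv_floor`; trimming stops at the
#' first clean segment. Interior segments are never excised. The trimmed
#' read is then accepted only if the kept length is at least
#' `min_keep_frac` of the original read and the mean QV of the kept bases
#' is at least `min_mean_qv`.
#'
#' @param read A quality read: a list with elements `residues` (string) and
#'   `qualities` (integer vector of per-base Phred scores), as produced by
#'   [read_quality_reads()] or [generate_quality_reads()]. A bare numeric
#'   vector of qualities is also accepted.
#' @param window Segment size in bases (default 20).
#' @param bad_per_window Number of sub-threshold bases that condemns a
#'   terminal segment (default 4, inclusive: ">= 4 bases below the floor").
#' @param qv_floor Per-base QV threshold (default 20).
#' @param min_keep_frac Minimum kept fraction of the original length
#'   (default 0.6).
#' @param min_mean_qv Minimum mean QV of the kept bases (default 30).
#' @return A list of class `qc_verdict`: `accepted`, `trimmed_span`
#'   (0-based half-open `c(start, end)`), `mean_qv` (over kept bases),
#'   `reasons` (character vector of failure codes among `"all_trimmed"`,
#'   `"too_short"`, `"low_mean_qv"`).
#' @examples
#' qv <- c(rep(10, 20), rep(40, 80))   # bad leading segment
#' v <- window_trim(qv)
#' v$trimmed_span   # c(20, 100): leading 20 bases removed
#' v$accepted       # TRUE: 80 bases kept at mean QV 40
#' @export
window_trim <- function(read, window = 20L, bad_per_window = 4L,
                        qv_floor = 20L, min_keep_frac = 0.6,
                        min_mean_qv = 30) {
  qv <- if (is.list(read)) read$qualities else read
  qv <- as.numeric(qv)
  n <- length(qv)
  if (n == 0L) stop("read must be non-empty")
  if (window < 1L) stop("window must be >= 1")
  w <- min(window, n)
  bad <- qv < qv_floor
  start <- 0L  # 0-based
  end <- n
  # trim whole segments from the left
  while (end - start >= 1L) {
    seg <- bad[(start + 1L):min(start + w, end)]
    if (sum(seg) >= bad_per_window) start <- start + length(seg) else break
  }
  # then from the right
  while (end - start >= 1L) {
    seg <- bad[max(end - w + 1L, start + 1L):end]
    if (sum(seg) >= bad_per_window) end <- end - length(seg) else break
  }
  reasons <- character(0)
  kept <- end - start
  mean_qv <- if (kept > 0L) mean(qv[(start + 1L):end]) else NA_real_
  if (kept == 0L) reasons <- c(reasons, "all_trimmed")
  if (kept < min_keep_frac * n) reasons <- c(reasons, "too_short")
  if (kept > 0L && mean_qv < min_mean_qv) reasons <- c(reasons, "low_mean_qv")
  structure(list(accepted = length(reasons) == 0L,
                 trimmed_span = c(start, end),
                 mean_qv = mean_qv,
                 reasons = reasons),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("QC verdict: %s; kept [%d, %d); mean QV %.1f%s\n",
              if (x$accepted) "accepted" else "rejected",
              x$trimmed_span[1], x$trimmed_span[2],
              x$mean_qv,
              if (length(x$reasons)) paste0("; reasons: ",
                                            paste(x$reasons, collapse = ",")) else ""))
  invisible(x)
}

#' Forward/reverse overlap coverage of a read pair
#'
#' The reverse read is reverse-complemented and locally aligned to the
#' forward read (Smith-Waterman, affine gaps). Coverage is the length of the
#' best local alignment divided by the length of the consensus span the two
#' reads would assemble into (`len(fwd) + len(rev) - overlap`). Bidirectional
#' pairs are conventionally usable when coverage exceeds 0.70, with a relaxed
#' floor of 0.50 admitted for a minority of templates.
#'
#' @param fwd Forward-read sequence (string).
#' @param rev Reverse-read sequence in its own read orientation; it is
#'   reverse-complemented internally.
#' @param match,mismatch,gap_open,gap_extend Local alignment scores
#'   (defaults +1/-1/-2/-2, i.e. a linear gap cost of -2 per base).
#' @return Coverage in `[0, 1]`, with attributes `overlap` (alignment
#'   columns) and `consensus_len`.
#' @examples
#' s <- paste(rep("ACGT", 50), collapse = "")
#' overlap_coverage(s, revcomp(s))  # 1.0
#' @export
overlap_coverage <- function(fwd, rev, match = 1, mismatch = -1,
                             gap_open = -2, gap_extend = -2) {
  if (!nzchar(fwd) || !nzchar(rev)) stop("sequences must be non-empty")
  al <- sw_align_cpp(toupper(fwd), revcomp(toupper(rev)),
                     match, mismatch, gap_open, gap_extend)
  ov <- al$length
  cons <- nchar(fwd) + nchar(rev) - ov
  cov <- ov / cons
  attr(cov, "overlap") <- ov
  attr(cov, "consensus_len") <- cons
  cov
}

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet and gaps.
#' @param x DNA string.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Screen an ITS sequence for the conserved 5.8S motif
#'
#' Angiosperm ITS sequences carry the conserved 5.8S rDNA motif
#' `GAATTGCAGAATCC`; the variant `GAATTGCAGAATTC` is characteristic of
#' fungi and flags probable endophyte contamination in a plant barcoding
#' data set. The search is an exact match on the forward strand.
#'
#' @param seq ITS or ITS2 sequence (string).
#' @return `"plant"`, `"fungal"` or `"absent"`. If both motifs occur the
#'   fungal call wins and a warning is raised.
#' @export
motif_screen <- function(seq) {
  s <- toupper(seq)
  plant <- grepl("GAATTGCAGAATCC", s, fixed = TRUE)
  fungal <- grepl("GAATTGCAGAATTC", s, fixed = TRUE)
  if (plant && fungal) {
    warning("both plant and fungal 5.8S motifs present; reporting 'fungal'")
    return("fungal")
  }
  if (fungal) return("fungal")
  if (plant) return("plant")
  "absent"
}

#' Read Sanger FASTQ reads with Phred qualities
#'
#' @param path FASTQ path (Sanger Phred+33 encoding).
#' @param direction Read direction to record: `"forward"`, `"reverse"`, or
#'   `"auto"` (default), which infers reverse reads from id suffixes
#'   `/2`, `_R` or `_rev`.
#' @return A list of quality reads, each a list with `read_id`, `residues`,
#'   `qualities`, `direction`.
#' @export
read_quality_reads <- function(path, direction = "auto") {
  dna <- ape::read.fastq(path)
  qual <- attr(dna, "QUAL")
  ids <- names(dna)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  lapply(seq_along(ids), function(i) {
    dir <- if (direction == "auto") {
      if (grepl("(/2|_R|_rev)$", ids[i])) "reverse" else "forward"
    } else direction
    list(read_id = ids[i], residues = seqs[[i]],
         qualities = as.integer(qual[[i]]), direction = dir)
  })
}

#' Write quality reads as Sanger FASTQ
#'
#' @param reads List of quality reads (see [read_quality_reads()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_quality_reads <- function(reads, path) {
  lines <- unlist(lapply(reads, function(r) {
    c(paste0("@", r$read_id), r$residues, "+",
      intToUtf8(pmin(r$qualities, 93L) + 33L, multiple = FALSE))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' QC report over a set of quality reads
#'
#' Runs [window_trim()] on every read and returns the tabular report used
#' by the pipeline (one row per read: kept span, mean QV, verdict, reasons).
#'
#' @param reads List of quality reads.
#' @inheritParams window_trim
#' @return A data frame with columns `read_id`, `direction`, `start`,
#'   `end`, `kept`, `mean_qv`, `accepted`, `reasons`.
#' @export
qc_report <- function(reads, window = 20L, bad_per_window = 4L,
                      qv_floor = 20L, min_keep_frac = 0.6,
                      min_mean_qv = 30) {
  rows <- lapply(reads, function(r) {
    v <- window_trim(r, window, bad_per_window, qv_floor,
                     min_keep_frac, min_mean_qv)
    data.frame(read_id = r$read_id,
               direction = if (is.null(r$direction)) NA_character_ else r$direction,
               start = v$trimmed_span[1], end = v$trimmed_span[2],
               kept = v$trimmed_span[2] - v$trimmed_span[1],
               mean_qv = v$mean_qv, accepted = v$accepted,
               reasons = paste(v$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
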