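# Candidate overlap detection: shared-k-mer seeding plus banded ends-free
# alignment, with hash-overlap-style thresholds (minimum overlap length 30,
# maximum disagreement rate 6%, counting mismatches + gap bases over
# alignment columns).

#' Index canonical k-mers of a read set
#'
#' Maps each canonical k-mer (lexicographic minimum of the k-mer and its
#' reverse complement) to all its occurrences.  Windows containing N are
#' skipped.  This is the seeding structure of the overlapper, exposed at
#' small scale for inspection; detection itself runs the equivalent index
#' in compiled code.
#'
#' @param reads Named DNAStringSet.
#' @param k Seed length (>= 2; >= 8 is sensible for real seeding).
#' @return A list keyed by canonical k-mer; each element is a data.frame
#'   with columns `read`, `pos` (0-based) and `strand` (`+` if the forward
#'   k-mer is canonical).
#' @export
indexKmers <- function(reads, k) {
  check_reads(reads)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > min(Biostrings::width(reads)))
    stop("k exceeds the shortest read", call. = FALSE)
  occ <- list()
  for (id in names(reads)) {
    seq <- as.character(reads[[id]])
    n <- nchar(seq) - k + 1L
    if (n < 1L) next
    kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    if (!any(ok)) next
    kk <- kmers[ok]
    rc <- rc_chr(kk)
    fwd_can <- kk <= rc
    canon <- ifelse(fwd_can, kk, rc)
    occ[[id]] <- data.frame(kmer = canon, read = id,
                            pos = which(ok) - 1L,
                            strand = ifelse(fwd_can, "+", "-"),
                            stringsAsFactors = FALSE)
  }
  if (!length(occ)) return(list())
  all <- do.call(rbind, occ)
  split(all[c("read", "pos", "strand")], all$kmer)
}

#' Find candidate overlaps between all read pairs
#'
#' Pairs sharing at least one canonical seed k-mer are aligned with a
#' banded ends-free (dovetail/containment) alignment around each
#' seed-implied offset; the best-scoring alignment per pair and
#' orientation is kept if it spans at least `minOverlap` columns with a
#' disagreement rate (mismatches + gap bases over columns) of at most
#' `maxError`.  Output is canonicalized (lexicographically smaller id
#' first) and deduplicated; a pair appears at most once per orientation.
#'
#' @param reads Named DNAStringSet.
#' @param k Seed k-mer length for detection (default 14).
#' @param minOverlap Minimum overlap length in alignment columns.
#' @param maxError Maximum disagreement rate.
#' @param band Initial alignment band half-width (doubled on demand).
#' @param maxBucket Seed k-mers occurring more often than this are skipped.
#' @return A data.frame with columns `readA, readB, orientation, a_hang,
#'   b_hang, overlap_length, matches, mismatches, gap_events, gap_bases,
#'   score`.  `a_hang` is the offset of readB's start in readA's forward
#'   frame; for flipped orientation readB is taken reverse-complemented.
#' @export
findOverlapCandidates <- function(reads, k = 14L, minOverlap = 30L,
                                  maxError = 0.06, band = 12L,
                                  maxBucket = 5000L) {
  check_reads(reads)
  if (k > min(Biostrings::width(reads)))
    stop("seed k exceeds the shortest read", call. = FALSE)
  raw <- cpp_find_overlaps(as.character(reads), as.integer(k),
                           as.integer(minOverlap), maxError,
                           as.integer(band), as.integer(maxBucket))
  ids <- names(reads)
  tbl <- data.frame(readA = ids[raw$readA], readB = ids[raw$readB],
                    orientation = ORIENTATIONS[raw$orient + 1L],
                    a_hang = raw$a_hang, b_hang = raw$b_hang,
                    overlap_length = raw$overlap_length,
                    matches = raw$matches, mismatches = raw$mismatches,
                    gap_events = raw$gap_events, gap_bases = raw$gap_bases,
                    score = raw$score, stringsAsFactors = FALSE)
  canonicalizeOverlaps(tbl)
}

#' Align two reads at a given overlap offset
#'
#' Computes the optimal banded ends-free alignment of `readA` against
#' `readB` (reverse-complemented when `orientation` is `"flipped"`) in a
#' band around `offset`, the putative start of readB in readA's frame.
#' The band is doubled automatically while the optimum touches its edge.
#'
#' @param readA,readB Character or DNAString sequences.
#' @param orientation `"same"` or `"flipped"`.
#' @param offset Seed-implied offset of readB's start in readA's frame.
#' @param band Initial band half-width.
#' @return A list with `a_hang, b_hang, overlap_length, matches,
#'   mismatches, gap_events, gap_bases, score`.
#' @export
alignOverlap <- function(readA, readB, orientation = "same", offset = 0L,
                         band = 12L) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  a <- toupper(as.character(readA))
  b <- toupper(as.character(readB))
  if (abs(offset) >= nchar(a) + nchar(b))
    stop("offset outside the alignable range", call. = FALSE)
  if (orientation == "flipped") b <- rc_chr(b)
  r <- cpp_align_overlap(a, b, as.integer(offset), as.integer(band))
  if (!r$ok) stop("alignment band exhausted", call. = FALSE)
  list(a_hang = r$i0 - r$j0,
       b_hang = (nchar(b) - r$j1) - (nchar(a) - r$i1),
       overlap_length = r$columns, matches = r$matches,
       mismatches = r$mismatches, gap_events = r$gap_events,
       gap_bases = r$gap_bases, score = r$score)
}
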