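# Ground-truth labelling of overlap candidates from known read source
# coordinates.

#' Label overlap candidates true or false
#'
#' A candidate is labelled `true` when some placement pair of its two
#' reads lies on the same genome, the source intervals intersect by at
#' least `minTrueOverlap` bp, and the strand relationship is consistent
#' with the candidate's orientation (same orientation requires equal
#' strands, flipped requires opposite).  Everything else, notably
#' repeat-induced alignments between reads from different loci, is
#' `false`.
#'
#' @param candidates Overlap table from [findOverlapCandidates()].
#' @param placements Named [GenomicRanges::GRanges] of true read
#'   placements, as produced by [simulateReads()]; multiple placements per
#'   read are allowed.
#' @param minTrueOverlap Minimum genomic intersection supporting a true
#'   label (default 30 bp, matching the overlapper's minimum overlap).
#' @return A data.frame with columns `readA, readB, orientation, label`
#'   (factor with levels `true, false`) and `genomic_overlap_bp`.
#' @export
labelOverlaps <- function(candidates, placements, minTrueOverlap = 30L) {
  candidates <- as.data.frame(candidates)
  ids <- names(placements)
  if (is.null(ids)) stop("placements must be named by read id", call. = FALSE)
  used <- unique(c(candidates$readA, candidates$readB))
  absent <- setdiff(used, ids)
  if (length(absent))
    stop("reads without placement: ",
         paste(head(absent, 5L), collapse = ", "), call. = FALSE)
  n <- nrow(candidates)
  if (!n) {
    return(data.frame(readA = character(0), readB = character(0),
                      orientation = character(0),
                      label = factor(character(0), levels = c("true", "false")),
                      genomic_overlap_bp = integer(0)))
  }
  pl <- data.frame(genome = as.character(GenomicRanges::seqnames(placements)),
                   start = GenomicRanges::start(placements),
                   end = GenomicRanges::end(placements),
                   strand = as.character(GenomicRanges::strand(placements)),
                   stringsAsFactors = FALSE)
  byread <- split(seq_len(nrow(pl)), ids)
  best <- integer(n)
  if (!anyDuplicated(ids)) {
    # fast path: exactly one placement per read (the simulator's case)
    ja <- match(candidates$readA, ids)
    jb <- match(candidates$readB, ids)
    same_genome <- pl$genome[ja] == pl$genome[jb]
    consistent <- ifelse(candidates$orientation == "same",
                         pl$strand[ja] == pl$strand[jb],
                         pl$strand[ja] != pl$strand[jb])
    inter <- pmin(pl$end[ja], pl$end[jb]) - pmax(pl$start[ja], pl$start[jb]) + 1L
    inter[!same_genome | !consistent] <- 0L
    best <- pmax(0L, inter)
    return(data.frame(readA = candidates$readA, readB = candidates$readB,
                      orientation = candidates$orientation,
                      label = factor(ifelse(best >= minTrueOverlap,
                                            "true", "false"),
                                     levels = c("true", "false")),
                      genomic_overlap_bp = best, stringsAsFactors = FALSE))
  }
  for (i in seq_len(n)) {
    ia <- byread[[candidates$readA[i]]]
    ib <- byread[[candidates$readB[i]]]
    ja <- rep(ia, each = length(ib))
    jb <- rep(ib, times = length(ia))
    same_genome <- pl$genome[ja] == pl$genome[jb]
    consistent <- if (candidates$orientation[i] == "same")
      pl$strand[ja] == pl$strand[jb]
    else pl$strand[ja] != pl$strand[jb]
    inter <- pmin(pl$end[ja], pl$end[jb]) - pmax(pl$start[ja], pl$start[jb]) + 1L
    inter[!same_genome | !consistent] <- 0L
    best[i] <- max(0L, inter)
  }
  data.frame(readA = candidates$readA, readB = candidates$readB,
             orientation = candidates$orientation,
             label = factor(ifelse(best >= minTrueOverlap, "true", "false"),
                            levels = c("true", "false")),
             genomic_overlap_bp = best, stringsAsFactors = FALSE)
}
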