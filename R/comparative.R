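# Comparative-genomics overlap score: both reads of a candidate are mapped
# to a panel of related genomes; the best co-placement (overlapping) and
# best discordant placement (non-overlapping) combination scores are
# contrasted on a signed log2 scale.

#' Map reads to a reference genome
#'
#' Seed-and-extend mapping on both strands: shared canonical 16-mers vote
#' for diagonals, each diagonal cluster is resolved with a banded fitting
#' alignment of the full read against the implied genome window, and hits
#' below the identity or coverage thresholds are discarded.
#'
#' @param reads Named DNAStringSet.
#' @param genome Length-1 named DNAStringSet.
#' @param mersize Seed length (default 16).
#' @param minIdentity Minimum alignment identity (matches over columns).
#' @param minCoverage Minimum fraction of the read aligned.
#' @param band Band half-width for the fitting alignment.
#' @param maxClusters Diagonal clusters examined per read and strand.
#' @return A [GenomicRanges::GRanges] of hits (1-based) with mcols
#'   `read_id, matching_bases, columns, identity, coverage`; minus strand
#'   means the reverse complement of the read matches the forward genome.
#' @export
mapReadToGenome <- function(reads, genome, mersize = 16L, minIdentity = 0.80,
                            minCoverage = 0.80, band = 32L,
                            maxClusters = 32L) {
  check_reads(reads)
  stopifnot(methods::is(genome, "DNAStringSet"), length(genome) == 1L)
  df <- cpp_map_reads(as.character(reads), as.character(genome[[1L]]),
                      as.integer(mersize), minIdentity, minCoverage,
                      as.integer(band), as.integer(maxClusters), 10000L)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(genome), nrow(df)),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$read_id <- names(reads)[df$read]
  gr$matching_bases <- df$matches
  gr$columns <- df$columns
  gr$identity <- df$identity
  gr$coverage <- df$coverage
  gr
}

# Hits as a plain data.frame with 0-based starts for combination math.
hits_df <- function(gr) {
  data.frame(read_id = gr$read_id,
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             matching_bases = gr$matching_bases,
             stringsAsFactors = FALSE)
}

# Implied a_hang of B relative to A from one placement pair, given the
# candidate orientation.  Returns NA when the strand relationship is
# inconsistent with the orientation.
implied_hang <- function(orientation, strandA, strandB,
                         startA, endA, startB, endB) {
  consistent <- if (orientation == "same") strandA == strandB
                else strandA != strandB
  out <- ifelse(strandA == "+", startB - startA, endA - endB)
  out[!consistent] <- NA_real_
  out
}

#' Enumerate placement combinations for one candidate on one genome
#'
#' Every (hit of readA, hit of readB) pair on the same genome is one
#' combination.  A combination is `overlapping` when the strand
#' relationship matches the candidate's orientation and the implied
#' relative offset agrees with the candidate's `a_hang` within
#' `tolerance`; otherwise it is `non-overlapping`.  The combination score
#' is the summed matching bases of the two hits.
#'
#' @param hitsA,hitsB GRanges of hits of readA and readB on one genome
#'   (as returned by [mapReadToGenome()]).
#' @param candidate One-row overlap candidate (list or data.frame row)
#'   with `orientation` and `a_hang`.
#' @param tolerance Offset tolerance in bp (default 30).
#' @return A data.frame with one row per combination: `hitA, hitB, class,
#'   combo_score`.
#' @export
enumerateCombinations <- function(hitsA, hitsB, candidate, tolerance = 30L) {
  a <- hits_df(hitsA)
  b <- hits_df(hitsB)
  if (!nrow(a) || !nrow(b)) {
    return(data.frame(hitA = integer(0), hitB = integer(0),
                      class = character(0), combo_score = numeric(0)))
  }
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  imp <- implied_hang(candidate$orientation, a$strand[ia], b$strand[ib],
                      a$start0[ia], a$end0[ia], b$start0[ib], b$end0[ib])
  ovl <- !is.na(imp) & abs(imp - candidate$a_hang) <= tolerance
  data.frame(hitA = ia, hitB = ib,
             class = ifelse(ovl, "overlapping", "non-overlapping"),
             combo_score = a$matching_bases[ia] + b$matching_bases[ib])
}

#' Comparative score from top combination scores
#'
#' `log2(maxOvl - maxNonovl + 1)` when the top overlapping combination
#' beats the top non-overlapping one, the negated mirror when it loses, 0
#' on a tie, and NA (undefined) when neither score exists, i.e. when one
#' or both reads did not map.  A score class absent while the other is
#' present counts as 0 support.
#'
#' @param maxOvl,maxNonovl Numeric vectors of top overlapping and top
#'   non-overlapping combination scores; NA marks an absent class.
#' @return Signed numeric score(s); NA where undefined.
#' @export
comparativeScore <- function(maxOvl, maxNonovl) {
  n <- max(length(maxOvl), length(maxNonovl))
  maxOvl <- rep_len(as.numeric(maxOvl), n)
  maxNonovl <- rep_len(as.numeric(maxNonovl), n)
  out <- rep(NA_real_, n)
  both_absent <- is.na(maxOvl) & is.na(maxNonovl)
  o <- ifelse(is.na(maxOvl), 0, maxOvl)
  v <- ifelse(is.na(maxNonovl), 0, maxNonovl)
  pos <- !both_absent & o > v
  neg <- !both_absent & o < v
  tie <- !both_absent & o == v
  out[pos] <- log2(o[pos] - v[pos] + 1)
  out[neg] <- -log2(v[neg] - o[neg] + 1)
  out[tie] <- 0
  out
}

#' Comparative evidence for overlap candidates
#'
#' Maps every read occurring in `candidates` to each genome of the panel,
#' enumerates placement combinations per genome, takes the maximum
#' overlapping and non-overlapping combination scores across the whole
#' panel and applies [comparativeScore()].  Candidates where either read
#' has no hit in any panel genome get a missing (NA) score.
#'
#' @param candidates Overlap table from [findOverlapCandidates()].
#' @param reads Named DNAStringSet.
#' @param genomePanel Named DNAStringSet of related genomes (or a list of
#'   length-1 DNAStringSets).
#' @param tolerance Offset tolerance in bp passed to the combination
#'   classifier.
#' @param ... Passed to [mapReadToGenome()].
#' @return A data.frame with columns `readA, readB, orientation,
#'   max_s_ovl, max_s_nonovl, comp_score` (NA where undefined).
#' @export
comparativeEvidence <- function(candidates, reads, genomePanel,
                                tolerance = 30L, ...) {
  candidates <- as.data.frame(candidates)
  if (methods::is(genomePanel, "DNAStringSet")) {
    genomePanel <- lapply(seq_along(genomePanel), function(i) {
      g <- genomePanel[i]
      g
    })
  }
  if (!length(genomePanel)) stop("empty genome panel", call. = FALSE)
  n <- nrow(candidates)
  if (!n) {
    return(data.frame(readA = character(0), readB = character(0),
                      orientation = character(0), max_s_ovl = numeric(0),
                      max_s_nonovl = numeric(0), comp_score = numeric(0)))
  }
  used <- unique(c(candidates$readA, candidates$readB))
  sub <- reads[used]
  max_ovl <- rep(NA_real_, n)
  max_non <- rep(NA_real_, n)
  mappedA <- rep(FALSE, n)
  mappedB <- rep(FALSE, n)
  for (g in genomePanel) {
    hits <- hits_df(mapReadToGenome(sub, g, ...))
    if (!nrow(hits)) next
    byread <- split(seq_len(nrow(hits)), hits$read_id)
    idxA <- byread[candidates$readA]
    idxB <- byread[candidates$readB]
    nA <- lengths(idxA)
    nB <- lengths(idxB)
    mappedA <- mappedA | nA > 0L
    mappedB <- mappedB | nB > 0L
    # fast path: unique placement for both reads
    fast <- which(nA == 1L & nB == 1L)
    if (length(fast)) {
      ha <- unlist(idxA[fast], use.names = FALSE)
      hb <- unlist(idxB[fast], use.names = FALSE)
      consistent <- ifelse(candidates$orientation[fast] == "same",
                           hits$strand[ha] == hits$strand[hb],
                           hits$strand[ha] != hits$strand[hb])
      raw <- ifelse(hits$strand[ha] == "+",
                    hits$start0[hb] - hits$start0[ha],
                    hits$end0[ha] - hits$end0[hb])
      sc <- hits$matching_bases[ha] + hits$matching_bases[hb]
      is_ovl <- consistent & abs(raw - candidates$a_hang[fast]) <= tolerance
      ovl_rows <- fast[is_ovl]
      max_ovl[ovl_rows] <- pmax(max_ovl[ovl_rows], sc[is_ovl], na.rm = TRUE)
      non_rows <- fast[!is_ovl]
      max_non[non_rows] <- pmax(max_non[non_rows], sc[!is_ovl], na.rm = TRUE)
    }
    multi <- which(nA > 0L & nB > 0L & !(nA == 1L & nB == 1L))
    for (i in multi) {
      ha <- idxA[[i]]
      hb <- idxB[[i]]
      ia <- rep(ha, each = length(hb))
      ib <- rep(hb, times = length(ha))
      consistent <- if (candidates$orientation[i] == "same")
        hits$strand[ia] == hits$strand[ib]
      else hits$strand[ia] != hits$strand[ib]
      raw <- ifelse(hits$strand[ia] == "+",
                    hits$start0[ib] - hits$start0[ia],
                    hits$end0[ia] - hits$end0[ib])
      sc <- hits$matching_bases[ia] + hits$matching_bases[ib]
      is_ovl <- consistent & abs(raw - candidates$a_hang[i]) <= tolerance
      if (any(is_ovl))
        max_ovl[i] <- max(max_ovl[i], sc[is_ovl], na.rm = TRUE)
      if (any(!is_ovl))
        max_non[i] <- max(max_non[i], sc[!is_ovl], na.rm = TRUE)
    }
  }
  score <- comparativeScore(max_ovl, max_non)
  score[!(mappedA & mappedB)] <- NA_real_
  data.frame(readA = candidates$readA, readB = candidates$readB,
             orientation = candidates$orientation,
             max_s_ovl = max_ovl, max_s_nonovl = max_non,
             comp_score = score, stringsAsFactors = FALSE)
}

#' Coarse whole-genome identity estimate from shared k-mers
#'
#' Estimates average nucleotide identity between two genomes as
#' `j^(1/k)` where `j` is the fraction of the first genome's canonical
#' k-mers found in the second.  Intended for panel selection by identity
#' cutoff, not for fine comparisons.
#'
#' @param genomeA,genomeB Length-1 DNAStringSets.
#' @param k k-mer length (default 16).
#' @return Estimated identity in \[0, 1\].
#' @export
estimateIdentity <- function(genomeA, genomeB, k = 16L) {
  ptrB <- cpp_kmer_build(as.character(genomeB[[1L]]), as.integer(k))
  counts <- cpp_kmer_window_counts(ptrB, as.character(genomeA[[1L]]),
                                   as.integer(k))[[1L]]
  if (!length(counts)) return(0)
  mean(counts > 0)^(1 / k)
}
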