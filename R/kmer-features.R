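# Non-comparative overlap features: alignment statistics and
# coverage-normalised k-mer frequency statistics.

#' KmerFrequencyModel
#'
#' Canonical k-mer occurrence counts over a read set, with the expected
#' sequencing coverage used to normalise frequencies (a unique genome
#' k-mer has normalised frequency around 1, repeat k-mers well above 1).
#' The count table lives in compiled code behind an external pointer; the
#' object is therefore not serialisable and should be rebuilt from the
#' reads when needed.
#'
#' @slot k k-mer length.
#' @slot ptr External pointer to the count hash.
#' @slot nKmers Number of distinct canonical k-mers.
#' @slot totalKmers Total k-mer occurrences counted.
#' @slot expectedCoverage Expected fold coverage used for normalisation.
#' @slot meanFrequency Mean normalised frequency over distinct k-mers.
#' @aliases KmerFrequencyModel
#' @exportClass KmerFrequencyModel
setClass("KmerFrequencyModel",
         representation(k = "integer", ptr = "externalptr",
                        nKmers = "numeric", totalKmers = "numeric",
                        expectedCoverage = "numeric",
                        meanFrequency = "numeric"))

setValidity("KmerFrequencyModel", function(object) {
  if (length(object@k) != 1L || object@k < 1L) return("invalid k")
  if (object@expectedCoverage <= 0) return("expectedCoverage must be > 0")
  if (object@nKmers < 1) return("model holds no k-mers")
  TRUE
})

setMethod("show", "KmerFrequencyModel", function(object) {
  cat("KmerFrequencyModel\n")
  cat(sprintf("  k: %d\n", object@k))
  cat(sprintf("  distinct canonical k-mers: %.0f\n", object@nKmers))
  cat(sprintf("  total occurrences: %.0f\n", object@totalKmers))
  cat(sprintf("  expected coverage: %.3g\n", object@expectedCoverage))
  cat(sprintf("  mean normalised frequency: %.4g\n", object@meanFrequency))
})

#' Build a k-mer frequency model from reads
#'
#' Counts all canonical k-mers in the read set.  The normalised frequency
#' of a k-mer is its count divided by `expectedCoverage`; when coverage is
#' not supplied it is estimated as total read bases over a genome-size
#' estimate (by default the number of distinct canonical k-mers).
#'
#' @param reads Named DNAStringSet.
#' @param k k-mer length (default 16).
#' @param expectedCoverage Expected fold coverage, if known.
#' @param genomeSize Genome size estimate used when `expectedCoverage` is
#'   `NULL`.
#' @return A [KmerFrequencyModel-class].
#' @export
buildKmerModel <- function(reads, k = 16L, expectedCoverage = NULL,
                           genomeSize = NULL) {
  check_reads(reads)
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be in 1..31", call. = FALSE)
  if (k > max(Biostrings::width(reads)))
    stop("k exceeds the longest read", call. = FALSE)
  ptr <- cpp_kmer_build(as.character(reads), k)
  s <- cpp_kmer_summary(ptr)
  if (s$n_distinct < 1) stop("no countable k-mers in reads", call. = FALSE)
  if (is.null(expectedCoverage)) {
    if (is.null(genomeSize)) genomeSize <- s$n_distinct
    expectedCoverage <- sum(Biostrings::width(reads)) / genomeSize
  }
  methods::new("KmerFrequencyModel", k = k, ptr = ptr,
               nKmers = s$n_distinct, totalKmers = s$total,
               expectedCoverage = as.numeric(expectedCoverage),
               meanFrequency = s$mean_count / expectedCoverage)
}

#' @describeIn buildKmerModel Raw canonical counts of specific k-mers
#'   (0 for unseen k-mers, NA for invalid ones).
#' @param model A KmerFrequencyModel.
#' @param kmers Character vector of k-mers to look up.
#' @export
kmerCounts <- function(model, kmers) {
  stopifnot(methods::is(model, "KmerFrequencyModel"))
  counts <- cpp_kmer_counts_of(model@ptr, toupper(kmers), model@k)
  names(counts) <- kmers
  counts
}

#' @describeIn buildKmerModel Full count table (canonical k-mer, count);
#'   intended for small models in tests and inspection.
#' @export
kmerTable <- function(model) {
  stopifnot(methods::is(model, "KmerFrequencyModel"))
  tbl <- cpp_kmer_dump(model@ptr, model@k)
  tbl[order(tbl$kmer), , drop = FALSE]
}

#' @describeIn buildKmerModel Expected coverage used for normalisation.
#' @export
expectedCoverage <- function(model) model@expectedCoverage

#' @describeIn buildKmerModel Mean normalised frequency over distinct
#'   k-mers (the overrepresentation threshold is 1.5 times this value).
#' @export
meanFrequency <- function(model) model@meanFrequency

#' k-mer frequency statistics of overlap regions
#'
#' For each candidate, collects the normalised frequencies of every k-mer
#' from both reads' overlapping substrings (a multiset, so the statistics
#' are invariant under swapping the reads), sorts them ascending and
#' reports the quartiles under the nearest-rank (lower) convention, the
#' fraction above 1.5 times the model's mean frequency (overrepresented
#' k-mers) and the number with raw count exactly 1 (likely sequencing
#' errors).  Candidates whose overlap region spans no full k-mer get NA
#' statistics.
#'
#' @param candidates Overlap table from [findOverlapCandidates()].
#' @param reads Named DNAStringSet the candidates refer to.
#' @param model A [KmerFrequencyModel-class] built from the same reads.
#' @return A data.frame with columns `kmer_q1, kmer_q2, kmer_q3,
#'   pct_overrepresented, n_singleton_kmers, n_kmers`.
#' @export
overlapKmerStats <- function(candidates, reads, model) {
  check_reads(reads)
  stopifnot(methods::is(model, "KmerFrequencyModel"))
  candidates <- as.data.frame(candidates)
  if (!nrow(candidates)) {
    out <- data.frame(kmer_q1 = numeric(0), kmer_q2 = numeric(0),
                      kmer_q3 = numeric(0), pct_overrepresented = numeric(0),
                      n_singleton_kmers = numeric(0), n_kmers = numeric(0))
    return(out)
  }
  seqs <- seqs_chr(reads)
  missing <- setdiff(unique(c(candidates$readA, candidates$readB)),
                     names(seqs))
  if (length(missing))
    stop("candidates reference unknown reads: ",
         paste(head(missing, 3L), collapse = ", "), call. = FALSE)
  sa <- seqs[candidates$readA]
  sb <- seqs[candidates$readB]
  flip <- candidates$orientation == "flipped"
  sb[flip] <- rc_chr(sb[flip])
  reg <- overlap_region(candidates$a_hang, candidates$b_hang,
                        nchar(sa), nchar(sb))
  subA <- substring(sa, reg$a_start + 1L, reg$a_end)
  subB <- substring(sb, reg$b_start + 1L, reg$b_end)
  m <- cpp_overlap_kmer_stats(model@ptr, subA, subB, model@k,
                              model@expectedCoverage, model@meanFrequency)
  as.data.frame(m)
}

#' Alignment-derived overlap features
#'
#' Percent mismatch (mismatches over overlap columns), percent identity
#' (matches over overlap columns), overlap length and the mismatch/gap
#' counts carried by the candidates.
#'
#' @param candidates Overlap table from [findOverlapCandidates()].
#' @return A data.frame with columns `pct_mismatch, pct_identity,
#'   overlap_length, n_mismatches, n_gap_events`.
#' @export
alignmentFeatures <- function(candidates) {
  candidates <- as.data.frame(candidates)
  need <- c("overlap_length", "mismatches", "gap_events", "matches")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidates lack alignment statistics: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(candidates$overlap_length <= 0))
    stop("overlap_length must be positive", call. = FALSE)
  data.frame(pct_mismatch = candidates$mismatches / candidates$overlap_length,
             pct_identity = candidates$matches / candidates$overlap_length,
             overlap_length = candidates$overlap_length,
             n_mismatches = candidates$mismatches,
             n_gap_events = candidates$gap_events)
}

#' Assemble the non-comparative feature table
#'
#' Binds the candidate keys, alignment features and k-mer statistics into
#' one table, one row per candidate.
#'
#' @inheritParams overlapKmerStats
#' @return A data.frame keyed by `readA, readB, orientation`.
#' @export
noncompFeatures <- function(candidates, reads, model) {
  candidates <- as.data.frame(candidates)
  keys <- candidates[c("readA", "readB", "orientation")]
  cbind(keys, alignmentFeatures(candidates),
        overlapKmerStats(candidates, reads, model))
}
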