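# Shared fixtures: small simulated datasets, an independent ends-free
# alignment oracle built on Biostrings::pairwiseAlignment, and a memoised
# standard-benchmark run used by the slower end-to-end tests.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

named_reads <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- sprintf("r%03d", seq_along(seqs))
  else names(x) <- names(seqs)
  x
}

# Small simulated dataset; error-free unless stated.
tiny_dataset <- function(seed = 5L, genome_length = 8000L, coverage = 8,
                         read_length_mean = 150L, read_length_sd = 15,
                         substitution_rate = 0, indel_rate = 0,
                         repeat_specs = NULL) {
  cfg <- simConfig(genome_length = genome_length, repeat_specs = repeat_specs,
                   coverage = coverage, read_length_mean = read_length_mean,
                   read_length_sd = read_length_sd,
                   substitution_rate = substitution_rate,
                   indel_rate = indel_rate, seed = seed)
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim$genome, cfg)
  list(config = cfg, genome = sim$genome, repeats = sim$repeats,
       reads = rd$reads, placements = rd$placements)
}

# Independent candidate-overlap oracle: optimal ends-free alignment for
# every read pair and orientation via Biostrings::pairwiseAlignment
# (type "overlap"), same scoring (match +1, mismatch -2, gap -3 linear)
# and the same acceptance thresholds as the overlapper.
oracle_overlaps <- function(reads, minOverlap = 30L, maxError = 0.06) {
  ids <- names(reads)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  out <- list()
  for (i in seq_along(reads)) {
    for (j in seq_along(reads)) {
      if (j <= i) next
      for (orient in c("same", "flipped")) {
        b <- reads[[j]]
        if (orient == "flipped") b <- Biostrings::reverseComplement(b)
        aln <- Biostrings::pairwiseAlignment(
          reads[[i]], b, type = "overlap", substitutionMatrix = mat,
          gapOpening = 0, gapExtension = 3)
        nm <- Biostrings::nmatch(aln)
        nmm <- Biostrings::nmismatch(aln)
        ind <- Biostrings::nindel(aln)
        gapb <- sum(Biostrings::insertion(ind)[[1L]]) +
          sum(Biostrings::deletion(ind)[[1L]])
        cols <- nm + nmm + gapb
        if (cols < minOverlap) next
        if (nmm + gapb > maxError * cols + 1e-9) next
        pa <- aln@pattern
        ps <- aln@subject
        a_hang <- Biostrings::start(pa) - Biostrings::start(ps)
        out[[length(out) + 1L]] <- data.frame(
          readA = ids[i], readB = ids[j], orientation = orient,
          a_hang = a_hang, overlap_length = cols, mismatches = nmm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(readA = character(0), readB = character(0),
                      orientation = character(0), a_hang = integer(0),
                      overlap_length = integer(0), mismatches = integer(0)))
  }
  tbl <- do.call(rbind, out)
  tbl[order(tbl$readA, tbl$readB, tbl$orientation), , drop = FALSE]
}

# Brute-force N50 oracle: try every candidate threshold; the N50 is the
# largest contig length whose tail-sum (all contigs at least that long)
# still reaches half the reference.
oracle_n50 <- function(lengths, ref_len) {
  if (!length(lengths)) return(0)
  feasible <- vapply(sort(unique(lengths)), function(l)
    sum(lengths[lengths >= l]) >= ref_len / 2, TRUE)
  cand <- sort(unique(lengths))[feasible]
  if (!length(cand)) return(0)
  max(cand)
}

# Memoised standard-benchmark pipeline runs shared by the end-to-end
# tests (the expensive part of the suite).
.bench_cache <- new.env(parent = emptyenv())
standard_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  bench <- makeBenchmark(seed = seed)
  trn <- overlapFeatureTable(bench$train$reads,
                             c("noncomparative", "comparative"),
                             bench$train$panel, bench$train$placements,
                             coverage = 10)
  tst <- overlapFeatureTable(bench$test$reads,
                             c("noncomparative", "comparative"),
                             bench$test$panel, bench$test$placements,
                             coverage = 10)
  rf <- trainClassifier(trn$features, algorithm = "random_forest", seed = 1L)
  pred_rf <- predictLabels(rf, tst$features[setdiff(names(tst$features),
                                                    "label")])
  uncorrected <- evaluateAssembly(bench$test$reads, tst$candidates,
                                  bench$test$genome)
  corrected <- evaluateAssembly(bench$test$reads,
                                filterOverlaps(tst$candidates, pred_rf),
                                bench$test$genome)
  out <- list(bench = bench, trn = trn, tst = tst, pred_rf = pred_rf,
              uncorrected = uncorrected, corrected = corrected)
  .bench_cache[[key]] <- out
  out
}
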