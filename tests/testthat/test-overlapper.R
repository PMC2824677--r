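test_that("k-mer indexing canonicalises, skips N and validates k", {
  reads <- named_reads(c(a = "ACGTACGT"))
  idx <- indexKmers(reads, 4L)
  expect_identical(sum(vapply(idx, nrow, 1L)), 5L)  # len - k + 1 positions

  # a k-mer and its reverse complement land in the same bucket
  reads2 <- named_reads(c(x = "AACCGGTTAG", y = "CTAACCGGTT"))
  idx2 <- indexKmers(reads2, 8L)
  shared <- idx2[vapply(idx2, function(d) length(unique(d$read)) == 2L, TRUE)]
  expect_true(length(shared) >= 1L)

  reads3 <- named_reads(c(n = "NNNNNNNNNNNN", a = "ACGTACGTACGT"))
  idx3 <- indexKmers(reads3, 8L)
  expect_false("n" %in% unlist(lapply(idx3, `[[`, "read")))

  expect_error(indexKmers(named_reads(c(s = "ACGTAC")), 8L), "shortest")
})

test_that("pairwise alignment statistics match constructed differences", {
  base <- random_seq(120, seed = 31)
  # identical substrings
  r <- alignOverlap(base, base, "same", 0L)
  expect_identical(r$mismatches, 0L)
  expect_identical(r$gap_events, 0L)
  expect_identical(r$overlap_length, 120L)
  # one substitution
  mut <- base
  substr(mut, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 60, 60))[1L]
  r <- alignOverlap(base, mut, "same", 0L)
  expect_identical(r$mismatches, 1L)
  # one length-2 insertion
  ins <- paste0(substr(base, 1, 60), "CA", substr(base, 61, 120))
  # guard the fixture against an ambiguous gap placement
  r <- alignOverlap(base, ins, "same", 0L)
  expect_identical(r$gap_bases, 2L)
  expect_identical(r$gap_events, 1L)
  expect_identical(r$overlap_length, 122L)
  expect_identical(r$mismatches, 0L)
})

test_that("alignment statistics agree with an independent aligner", {
  set.seed(41)
  for (rep in 1:10) {
    a <- random_seq(150)
    b <- paste0(substr(a, 71, 150),
                random_seq(70))
    # sprinkle a couple of substitutions into the shared part
    bb <- strsplit(b, "")[[1L]]
    pos <- sample(5:75, 2)
    bb[pos] <- vapply(bb[pos],
                      function(x) setdiff(c("A", "C", "G", "T"), x)[1L], "")
    b <- paste(bb, collapse = "")
    got <- alignOverlap(a, b, "same", 70L)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 3)
    expect_identical(got$score, as.integer(Biostrings::score(aln)))
    expect_identical(got$mismatches, Biostrings::nmismatch(aln))
  }
})

test_that("candidate detection finds dovetails, containments and thresholds", {
  set.seed(51)
  a <- random_seq(100)
  reads <- named_reads(c(p = a, q = a))
  cand <- findOverlapCandidates(reads, k = 10L)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$overlap_length, 100L)
  expect_identical(cand$mismatches, 0L)
  expect_identical(cand$a_hang, 0L)
  expect_identical(cand$b_hang, 0L)

  # exact 50 bp suffix-prefix dovetail
  left <- random_seq(120)
  right <- paste0(substr(left, 71, 120), random_seq(70))
  cand <- findOverlapCandidates(named_reads(c(a = left, b = right)), k = 10L)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$a_hang, 70L)
  expect_identical(cand$overlap_length, 50L)
  expect_identical(cand$mismatches, 0L)

  # a shared region below the minimum overlap yields nothing
  short <- paste0(substr(left, 92, 120), random_seq(90))
  cand <- findOverlapCandidates(named_reads(c(a = left, b = short)), k = 10L)
  expect_identical(nrow(cand), 0L)
})

test_that("candidate set is invariant under read order and symmetric", {
  ds <- tiny_dataset(seed = 61, genome_length = 4000L,
                     read_length_mean = 120L)
  reads <- ds$reads
  cand1 <- findOverlapCandidates(reads)
  cand2 <- findOverlapCandidates(rev(reads))
  rownames(cand1) <- rownames(cand2) <- NULL
  expect_equal(cand2, cand1)
})

test_that("error-free overlapping pairs are all detected (sensitivity one)", {
  ds <- tiny_dataset(seed = 71, genome_length = 6000L, coverage = 6,
                     read_length_mean = 150L)
  cand <- findOverlapCandidates(ds$reads)
  lab <- labelOverlaps(cand, ds$placements)
  expect_true(all(lab$label == "true"))
  # every truly overlapping pair (>= 30 bp, consistent strands) is found
  pl <- ds$placements
  ids <- names(pl)
  found <- paste(cand$readA, cand$readB)
  n_missed <- 0L
  for (i in seq_along(pl)) {
    for (j in seq_along(pl)) {
      if (j <= i) next
      inter <- min(GenomicRanges::end(pl)[i], GenomicRanges::end(pl)[j]) -
        max(GenomicRanges::start(pl)[i], GenomicRanges::start(pl)[j]) + 1L
      if (inter < 30L) next
      key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
      if (!key %in% found) n_missed <- n_missed + 1L
    }
  }
  expect_identical(n_missed, 0L)
})
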