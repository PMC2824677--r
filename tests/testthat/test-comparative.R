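mk_hits <- function(genome, starts, ends, strands, matches, ids) {
  gr <- GenomicRanges::GRanges(genome, IRanges::IRanges(starts, ends),
                               strand = strands)
  gr$read_id <- ids
  gr$matching_bases <- matches
  gr$columns <- matches
  gr$identity <- 1
  gr$coverage <- 1
  gr
}

test_that("read mapping recovers exact and reverse-complement placements", {
  g <- named_reads(c(gen = random_seq(6000, seed = 101)))
  sub <- substr(as.character(g[[1L]]), 2001, 2400)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  reads <- named_reads(c(fw = sub, rv = rc))
  hits <- mapReadToGenome(reads, g)
  hf <- hits[hits$read_id == "fw"]
  expect_identical(length(hf), 1L)
  expect_identical(GenomicRanges::start(hf), 2001L)
  expect_identical(GenomicRanges::end(hf), 2400L)
  expect_identical(hf$identity, 1)
  expect_identical(hf$matching_bases, 400L)
  hr <- hits[hits$read_id == "rv"]
  expect_identical(as.character(GenomicRanges::strand(hr)), "-")
  expect_identical(GenomicRanges::start(hr), 2001L)

  # a read at 25% divergence falls below the identity threshold
  far <- strsplit(sub, "")[[1L]]
  set.seed(3)
  idx <- sample(400, 100)
  far[idx] <- vapply(far[idx],
                     function(x) setdiff(c("A", "C", "G", "T"), x)[1L], "")
  hits2 <- mapReadToGenome(named_reads(c(d = paste(far, collapse = ""))), g)
  expect_identical(length(hits2), 0L)
})

test_that("the two-placement example yields two overlapping and two
           non-overlapping combinations", {
  # reads A and B overlap; each maps twice, at repeat copies X and Y
  hitsA <- mk_hits("g", c(1001, 5001), c(1400, 5400), "+", c(400, 395), "A")
  hitsB <- mk_hits("g", c(1201, 5201), c(1600, 5600), "+", c(400, 390), "B")
  cand <- list(orientation = "same", a_hang = 200L)
  combos <- enumerateCombinations(hitsA, hitsB, cand, tolerance = 30L)
  expect_identical(nrow(combos), 4L)
  expect_identical(sum(combos$class == "overlapping"), 2L)
  expect_identical(sum(combos$class == "non-overlapping"), 2L)
  # scores are summed matching bases
  expect_setequal(combos$combo_score[combos$class == "overlapping"],
                  c(800, 785))

  # single consistent placement pair
  c1 <- enumerateCombinations(hitsA[1], hitsB[1], cand)
  expect_identical(c1$class, "overlapping")
  # strand-inconsistent placements cannot support a same-orientation overlap
  hitsBneg <- mk_hits("g", 1201, 1600, "-", 400, "B")
  c2 <- enumerateCombinations(hitsA[1], hitsBneg, cand)
  expect_identical(c2$class, "non-overlapping")
  # combination count is always |hitsA| x |hitsB|
  expect_identical(nrow(enumerateCombinations(hitsA, hitsBneg, cand)), 2L)
})

test_that("comparative score follows the signed log2 margin", {
  expect_identical(comparativeScore(750, 750), 0)
  expect_identical(comparativeScore(107, 100), 3)
  expect_identical(comparativeScore(100, 103), -2)
  # an absent class counts as zero support
  expect_identical(comparativeScore(7, NA), 3)
  expect_identical(comparativeScore(NA, 7), -3)
  expect_true(is.na(comparativeScore(NA, NA)))
  # antisymmetry and monotonicity
  set.seed(7)
  a <- sample(0:2000, 200, replace = TRUE)
  b <- sample(0:2000, 200, replace = TRUE)
  expect_equal(comparativeScore(a, b), -comparativeScore(b, a))
  expect_identical(comparativeScore(a, a), rep(0, 200))
  margins <- sort(unique(a - b))
  sc <- comparativeScore(1000 + margins, 1000)
  expect_true(all(diff(sc) > 0))
})

test_that("comparative evidence separates co-placed from discordant pairs", {
  set.seed(111)
  unit <- random_seq(500)
  # panel genome with two 10%-diverged copies of the unit
  mutate <- function(s, p) {
    v <- strsplit(s, "")[[1L]]
    idx <- which(runif(length(v)) < p)
    v[idx] <- vapply(v[idx],
                     function(x) setdiff(c("A", "C", "G", "T"), x)[1L], "")
    paste(v, collapse = "")
  }
  c1 <- unit
  c2 <- mutate(unit, 0.10)
  panel <- named_reads(c(rel = paste0(random_seq(800), c1, random_seq(700),
                                      c2, random_seq(800))))
  # a false candidate: readA from copy 1, readB from copy 2, paired as if
  # they overlapped at one locus
  readA <- substr(c1, 1, 300)
  readB <- substr(c2, 101, 400)
  cand <- data.frame(readA = "a", readB = "b", orientation = "same",
                     a_hang = 100L, b_hang = 100L, overlap_length = 200L,
                     matches = 200L, mismatches = 0L, gap_events = 0L,
                     gap_bases = 0L, stringsAsFactors = FALSE)
  reads <- named_reads(c(a = readA, b = readB))
  ev <- comparativeEvidence(cand, reads, list(panel))
  expect_true(ev$max_s_nonovl > ev$max_s_ovl)
  expect_true(ev$comp_score < 0)

  # a true candidate at a unique locus scores positive
  g2 <- named_reads(c(rel2 = random_seq(3000)))
  ra <- substr(as.character(g2[[1L]]), 1001, 1300)
  rb <- substr(as.character(g2[[1L]]), 1101, 1400)
  cand2 <- cand
  cand2$a_hang <- 100L
  ev2 <- comparativeEvidence(cand2, named_reads(c(a = ra, b = rb)), list(g2))
  expect_true(ev2$comp_score > 0)

  # a read that maps nowhere leaves the score undefined
  ev3 <- comparativeEvidence(cand2,
                             named_reads(c(a = ra, b = random_seq(300))),
                             list(g2))
  expect_true(is.na(ev3$comp_score))
})
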