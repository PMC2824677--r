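test_that("genome simulation is deterministic and plants exact repeats", {
  cfg <- simConfig(genome_length = 1000L, seed = 7L)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(Biostrings::width(g1$genome)[1L], 1000L)

  cfg <- simConfig(genome_length = 20000L,
                   repeat_specs = data.frame(unit_length = 200L,
                                             copy_number = 3L,
                                             divergence = 0),
                   seed = 9L)
  sim <- simulateGenome(cfg)
  expect_identical(length(sim$repeats), 3L)
  g <- as.character(sim$genome[[1L]])
  copies <- substring(g, GenomicRanges::start(sim$repeats),
                      GenomicRanges::end(sim$repeats))
  expect_identical(unique(nchar(copies)), 200L)
  expect_identical(copies[2L], copies[1L])
  expect_identical(copies[3L], copies[1L])
})

test_that("repeat copy divergence matches the mutation model", {
  cfg <- simConfig(genome_length = 100000L,
                   repeat_specs = data.frame(unit_length = 5000L,
                                             copy_number = 3L,
                                             divergence = 0.05),
                   seed = 13L)
  sim <- simulateGenome(cfg)
  g <- as.character(sim$genome[[1L]])
  copies <- substring(g, GenomicRanges::start(sim$repeats),
                      GenomicRanges::end(sim$repeats))
  # two copies independently substituted at p = 0.05 from a shared unit
  # differ per position with probability 2*p*(1-p) + p^2*(2/3)
  pdiff <- function(a, b) {
    mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }
  d <- c(pdiff(copies[1], copies[2]), pdiff(copies[1], copies[3]),
         pdiff(copies[2], copies[3]))
  expected <- 2 * 0.05 * 0.95 + 0.05^2 * 2 / 3
  expect_true(all(abs(d - expected) < 0.015))
})

test_that("related genomes realise the requested divergence", {
  cfg <- simConfig(genome_length = 100000L, seed = 21L)
  sim <- simulateGenome(cfg)
  rel <- deriveRelatedGenome(sim$genome, 0.09, seed = 2L, indel_rate = 0)
  # verify by direct positional comparison, independent of the reported value
  a <- strsplit(as.character(sim$genome[[1L]]), "")[[1L]]
  b <- strsplit(as.character(rel[[1L]]), "")[[1L]]
  ident <- mean(a == b)
  expect_true(abs(ident - 0.91) < 0.005)
  expect_equal(S4Vectors::mcols(rel)$identity, ident, tolerance = 1e-12)

  same <- deriveRelatedGenome(sim$genome, 0, seed = 2L, indel_rate = 0)
  expect_identical(as.character(same[[1L]]), as.character(sim$genome[[1L]]))

  rel2 <- deriveRelatedGenome(sim$genome, 0.09, seed = 3L, indel_rate = 0)
  expect_false(as.character(rel2[[1L]]) == as.character(rel[[1L]]))
})

test_that("simulated reads hit the coverage target and honour placements", {
  cfg <- simConfig(genome_length = 100000L, coverage = 10,
                   read_length_mean = 400, read_length_sd = 40,
                   substitution_rate = 0, indel_rate = 0, seed = 17L)
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim$genome, cfg)
  total <- sum(Biostrings::width(rd$reads))
  expect_true(abs(total - 1e6) / 1e6 < 0.02)

  # error-free reads re-extract exactly from their source interval
  g <- as.character(sim$genome[[1L]])
  pl <- rd$placements
  ext <- substring(g, GenomicRanges::start(pl), GenomicRanges::end(pl))
  neg <- as.character(GenomicRanges::strand(pl)) == "-"
  ext[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ext[neg])))
  expect_identical(unname(as.character(rd$reads)), unname(ext))

  # determinism
  rd2 <- simulateReads(sim$genome, cfg)
  expect_identical(as.character(rd2$reads), as.character(rd$reads))
})

test_that("empirical read error rates converge to the configured rates", {
  cfg <- simConfig(genome_length = 50000L, coverage = 8,
                   read_length_mean = 300, read_length_sd = 0,
                   substitution_rate = 0.02, indel_rate = 0, seed = 23L)
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim$genome, cfg)
  g <- as.character(sim$genome[[1L]])
  pl <- rd$placements
  ext <- substring(g, GenomicRanges::start(pl), GenomicRanges::end(pl))
  neg <- as.character(GenomicRanges::strand(pl)) == "-"
  ext[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ext[neg])))
  obs <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }, as.character(rd$reads), ext)
  expect_true(abs(mean(obs) - 0.02) < 0.002)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(substitution_rate = 1.2), "rates")
  expect_error(simConfig(coverage = 0), "coverage")
  expect_error(simConfig(genome_length = 100L,
                         repeat_specs = data.frame(unit_length = 200L,
                                                   copy_number = 1L,
                                                   divergence = 0)),
               "exceed")
  cfg <- simConfig(genome_length = 500L,
                   repeat_specs = data.frame(unit_length = 400L,
                                             copy_number = 5L,
                                             divergence = 0),
                   seed = 1L)
  expect_error(simulateGenome(cfg), "copy_number")
  cfg2 <- simConfig(genome_length = 200L, read_length_mean = 400, seed = 1L)
  sim <- simulateGenome(simConfig(genome_length = 200L, seed = 1L))
  expect_error(simulateReads(sim$genome, cfg2), "incompatible")
})
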