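# Synthetic genomes, related strains and shotgun reads with known source
# coordinates.  Background composition is uniform over A/C/G/T so that the
# planted repeat families are the only source of homology.

#' Simulation configuration
#'
#' Collects the knobs for [simulateGenome()] and [simulateReads()].
#'
#' @param genome_length Genome length in bp.
#' @param repeat_specs data.frame with columns `unit_length` (bp),
#'   `copy_number` and `divergence` (per-copy substitution fraction), one
#'   row per repeat family; may be `NULL` for a repeat-free genome.
#' @param related_divergence Numeric vector of per-base divergence
#'   fractions for the related-genome panel (0.09 gives roughly 91%
#'   identity).
#' @param coverage Target fold coverage of the read set.
#' @param read_length_mean,read_length_sd Read length distribution (bp).
#' @param substitution_rate,indel_rate Per-base read error fractions;
#'   indels are length 1.
#' @param seed Integer seed making all outputs reproducible.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(genome_length = 50000L,
                      repeat_specs = NULL,
                      related_divergence = numeric(0),
                      coverage = 10,
                      read_length_mean = 400,
                      read_length_sd = 40,
                      substitution_rate = 0.01,
                      indel_rate = 0.003,
                      seed = 1L) {
  rates <- c(substitution_rate, indel_rate, related_divergence)
  if (any(rates < 0 | rates >= 1))
    stop("all rates must be in [0, 1)", call. = FALSE)
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (!is.null(repeat_specs)) {
    repeat_specs <- as.data.frame(repeat_specs)
    stopifnot(all(c("unit_length", "copy_number", "divergence") %in%
                    names(repeat_specs)))
    if (any(repeat_specs$unit_length >= genome_length))
      stop("genome_length must exceed the largest repeat unit", call. = FALSE)
  }
  structure(list(genome_length = as.integer(genome_length),
                 repeat_specs = repeat_specs,
                 related_divergence = related_divergence,
                 coverage = coverage,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each base independently with probability `rate` (always to a
# different base).  Returns list(seq, n_sub).
mutate_subs <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L))
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(list(seq = seq, n_sub = 0L))
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- ceiling(runif(length(hit)) * 3)
  bases[hit] <- vapply(seq_along(hit),
                       function(i) alt[[bases[hit[i]]]][pick[i]], "")
  list(seq = paste(bases, collapse = ""), n_sub = length(hit))
}

# Apply length-1 insertions and deletions at `rate` per base each way split
# evenly.  Returns list(seq, n_ins, n_del).
mutate_indels <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_ins = 0L, n_del = 0L))
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  u <- runif(n)
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  out <- bases
  out[del] <- ""
  if (any(ins)) {
    newb <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
    out[ins] <- paste0(newb, bases[ins])
  }
  list(seq = paste(out, collapse = ""), n_ins = sum(ins), n_del = sum(del))
}

#' Simulate a genome containing repeat families
#'
#' Generates a uniform-random genome and plants the configured repeat
#' copies at non-overlapping positions; each copy is independently
#' substituted at its family's divergence.
#'
#' @param config A [simConfig()] object.
#' @return A list with `genome` (named length-1
#'   [Biostrings::DNAStringSet]) and `repeats` (a
#'   [GenomicRanges::GRanges] of planted copies with mcols `family` and
#'   `copy`).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(child_seed(config$seed, 1L), {
    L <- config$genome_length
    genome <- random_dna(L)
    fam <- integer(0); cp <- integer(0); st <- integer(0); en <- integer(0)
    if (!is.null(config$repeat_specs) && nrow(config$repeat_specs)) {
      occupied <- IRanges::IRanges()
      for (f in seq_len(nrow(config$repeat_specs))) {
        spec <- config$repeat_specs[f, ]
        unit <- random_dna(spec$unit_length)
        for (copy in seq_len(spec$copy_number)) {
          placed <- FALSE
          for (try in 1:200) {
            pos <- sample.int(L - spec$unit_length + 1L, 1L)
            cand <- IRanges::IRanges(pos, pos + spec$unit_length - 1L)
            if (!length(IRanges::findOverlaps(cand, occupied))) {
              occupied <- c(occupied, cand)
              mut <- mutate_subs(unit, spec$divergence)
              substr(genome, pos, pos + spec$unit_length - 1L) <- mut$seq
              fam <- c(fam, f); cp <- c(cp, copy)
              st <- c(st, pos); en <- c(en, pos + spec$unit_length - 1L)
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("could not place repeat copies without overlap; ",
                 "reduce copy_number or unit_length", call. = FALSE)
        }
      }
    }
    gname <- sprintf("genome_s%d", config$seed)
    gset <- Biostrings::DNAStringSet(genome)
    names(gset) <- gname
    reps <- GenomicRanges::GRanges(
      seqnames = rep(gname, length(st)),
      ranges = IRanges::IRanges(start = st, end = en))
    reps$family <- fam
    reps$copy <- cp
    list(genome = gset, repeats = reps)
  })
}

#' Derive a related genome at a given divergence
#'
#' Applies independent per-base substitutions at `divergence` plus rare
#' length-1 indels (`indel_rate`, default `divergence / 100`).  The
#' realized substitution identity is attached as `mcols(x)$identity`.
#'
#' @param genome A length-1 named DNAStringSet.
#' @param divergence Substitution fraction in \[0, 0.5).
#' @param seed Integer seed.
#' @param indel_rate Per-base indel fraction.
#' @param name Name of the derived genome.
#' @return A length-1 named DNAStringSet with an `identity` metadata
#'   column.
#' @export
deriveRelatedGenome <- function(genome, divergence, seed = 1L,
                                indel_rate = divergence / 100,
                                name = NULL) {
  stopifnot(methods::is(genome, "DNAStringSet"), length(genome) == 1L)
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)", call. = FALSE)
  with_seed(seed, {
    seq <- as.character(genome[[1L]])
    sub <- mutate_subs(seq, divergence)
    ind <- mutate_indels(sub$seq, indel_rate)
    out <- Biostrings::DNAStringSet(ind$seq)
    names(out) <- if (is.null(name))
      sprintf("%s_rel%g", names(genome), divergence) else name
    S4Vectors::mcols(out)$identity <- 1 - sub$n_sub / nchar(seq)
    out
  })
}

#' Simulate shotgun reads with known source coordinates
#'
#' Reads are sampled uniformly over the genome with random strand; lengths
#' are normal (truncated to at least `min_length`); substitution and
#' length-1 indel errors are applied after extraction.  The number of reads
#' is chosen so total sampled bases approximate `coverage * genome_length`.
#'
#' @param genome A length-1 named DNAStringSet.
#' @param config A [simConfig()] object.
#' @param min_length Lower truncation for read lengths (bp).
#' @param prefix Read id prefix.
#' @return A list with `reads` (named DNAStringSet) and `placements` (a
#'   named [GenomicRanges::GRanges] of error-free source intervals, minus
#'   strand meaning the read is the reverse complement of the forward
#'   genome interval).
#' @export
simulateReads <- function(genome, config, min_length = 30L, prefix = "r") {
  stopifnot(methods::is(genome, "DNAStringSet"), length(genome) == 1L,
            inherits(config, "SimConfig"))
  L <- Biostrings::width(genome)[1L]
  if (config$read_length_mean > L)
    stop("read length distribution incompatible with genome length",
         call. = FALSE)
  with_seed(child_seed(config$seed, 2L), {
    n <- max(1L, round(config$coverage * L / config$read_length_mean))
    len <- round(rnorm(n, config$read_length_mean, config$read_length_sd))
    len <- pmin(pmax(len, min_length), L)
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gseq <- as.character(genome[[1L]])
    raw <- substring(gseq, start, start + len - 1L)
    rev <- strand == "-"
    raw[rev] <- rc_chr(raw[rev])
    out <- character(n)
    for (i in seq_len(n)) {
      s <- mutate_subs(raw[i], config$substitution_rate)$seq
      out[i] <- mutate_indels(s, config$indel_rate)$seq
    }
    ids <- sprintf("%s%06d", prefix, seq_len(n))
    reads <- Biostrings::DNAStringSet(out)
    names(reads) <- ids
    placements <- GenomicRanges::GRanges(
      seqnames = rep(names(genome), n),
      ranges = IRanges::IRanges(start = start, width = len),
      strand = strand)
    names(placements) <- ids
    list(reads = reads, placements = placements)
  })
}
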