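# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a stream label, staying < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seqs_chr <- function(reads) {
  x <- as.character(reads)
  names(x) <- names(reads)
  x
}

# Validate that `reads` is a named DNAStringSet with unique ids.
check_reads <- function(reads, what = "reads") {
  if (!methods::is(reads, "DNAStringSet"))
    stop(what, " must be a DNAStringSet", call. = FALSE)
  ids <- names(reads)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop(what, " must have non-empty names", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate ", what, " id: ", ids[duplicated(ids)][1L], call. = FALSE)
  invisible(reads)
}

OVERLAP_COLUMNS <- c("readA", "readB", "orientation", "a_hang", "b_hang",
                     "overlap_length", "mismatches", "gap_events")

ORIENTATIONS <- c("same", "flipped")

# Overlap substring intervals (0-based half-open) within each read's own
# oriented frame, from the hang coordinates.
overlap_region <- function(a_hang, b_hang, lenA, lenB) {
  list(a_start = pmax(a_hang, 0L),
       a_end   = lenA + pmin(b_hang, 0L),
       b_start = pmax(-a_hang, 0L),
       b_end   = lenB + pmin(-b_hang, 0L))
}
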