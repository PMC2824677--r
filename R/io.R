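#' Read a FASTA file of reads or genomes
#'
#' Reads a multi-record FASTA file, uppercases sequences, maps U to T and
#' any IUPAC ambiguity code to N.  Record ids are the first whitespace
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 a read", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L], call. = FALSE)
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id: ", ids[nchar(seqs) == 0L][1L], call. = FALSE)
  iupac <- "ACGTNRYSWKMBDHV"
  bad <- regexpr(sprintf("[^%s]", iupac), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
         call. = FALSE)
  }
  # ambiguity codes other than N carry no information for overlap scoring
  seqs <- chartr("RYSWKMBDHV", strrep("N", 10L), seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  check_reads(x, "sequences")
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Overlap tables
# ---------------------------------------------------------------------------

#' Validate and canonicalize an overlap table
#'
#' Rows are put in canonical form: `readA` is the lexicographically smaller
#' id; swapping the reads of a same-orientation overlap negates both hangs,
#' swapping a flipped overlap exchanges them.  Duplicate
#' (readA, readB, orientation) rows keep the first occurrence.  The
#' operation is idempotent.
#'
#' @param tbl A data.frame with at least the columns
#'   `readA, readB, orientation, a_hang, b_hang, overlap_length,
#'   mismatches, gap_events`.
#' @return The canonicalized data.frame, row-sorted by key.
#' @export
canonicalizeOverlaps <- function(tbl) {
  tbl <- as.data.frame(tbl)
  miss <- setdiff(OVERLAP_COLUMNS, names(tbl))
  if (length(miss))
    stop("overlap table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(tbl$orientation %in% ORIENTATIONS))
    stop("orientation must be one of: ", paste(ORIENTATIONS, collapse = ", "),
         call. = FALSE)
  swap <- tbl$readA > tbl$readB
  if (any(swap)) {
    a <- tbl$readA[swap]
    tbl$readA[swap] <- tbl$readB[swap]
    tbl$readB[swap] <- a
    same <- swap & tbl$orientation == "same"
    tbl$a_hang[same] <- -tbl$a_hang[same]
    tbl$b_hang[same] <- -tbl$b_hang[same]
    flip <- swap & tbl$orientation == "flipped"
    ah <- tbl$a_hang[flip]
    tbl$a_hang[flip] <- tbl$b_hang[flip]
    tbl$b_hang[flip] <- ah
  }
  key <- paste(tbl$readA, tbl$readB, tbl$orientation, sep = "\r")
  tbl <- tbl[!duplicated(key), , drop = FALSE]
  tbl <- tbl[order(tbl$readA, tbl$readB, tbl$orientation), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}

#' Write an overlap table as TSV
#'
#' Tab-separated with a single `#`-prefixed header line naming the columns.
#'
#' @param tbl Overlap table (see [canonicalizeOverlaps()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOverlaps <- function(tbl, path) {
  tbl <- as.data.frame(tbl)
  miss <- setdiff(OVERLAP_COLUMNS, names(tbl))
  if (length(miss))
    stop("overlap table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tbl), collapse = "\t")), con)
  if (nrow(tbl))
    write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read an overlap table written by [writeOverlaps()]
#'
#' @param path Path to the TSV file.
#' @param minOverlap Minimum admissible `overlap_length`; shorter rows are
#'   an error.
#' @return A data.frame of overlap candidates.
#' @export
readOverlaps <- function(path, minOverlap = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop("missing '#' header line in ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    tbl <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    for (nm in setdiff(cols, c("readA", "readB", "orientation")))
      tbl[[nm]] <- numeric(0)
    return(tbl)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(cols)))
    stop("malformed overlap row at line ",
         which(nfield != length(cols))[1L] + 1L, call. = FALSE)
  tbl <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tbl) <- cols
  for (nm in setdiff(cols, c("readA", "readB", "orientation"))) {
    val <- suppressWarnings(as.numeric(tbl[[nm]]))
    if (anyNA(val) && !all(is.na(tbl[[nm]]) | tbl[[nm]] == "NA"))
      stop("malformed numeric field '", nm, "' at line ",
           which(is.na(val) & tbl[[nm]] != "NA")[1L] + 1L, call. = FALSE)
    tbl[[nm]] <- val
  }
  miss <- setdiff(OVERLAP_COLUMNS, names(tbl))
  if (length(miss))
    stop("overlap table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(tbl$overlap_length < minOverlap | tbl$overlap_length < 0 |
                 tbl$mismatches < 0 | tbl$gap_events < 0)
  if (length(bad))
    stop("invalid overlap statistics at line ", bad[1L] + 1L, call. = FALSE)
  if (!all(tbl$orientation %in% ORIENTATIONS))
    stop("invalid orientation value in ", path, call. = FALSE)
  tbl
}

# ---------------------------------------------------------------------------
# Read placements
# ---------------------------------------------------------------------------

#' Write read placements as TSV
#'
#' Placements are stored 1-based in memory ([GenomicRanges::GRanges]) and
#' written 0-based half-open on disk.
#'
#' @param placements A GRanges named by read id; seqnames are genome ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePlacements <- function(placements, path) {
  df <- data.frame(
    read_id = names(placements),
    genome_id = as.character(GenomicRanges::seqnames(placements)),
    start = GenomicRanges::start(placements) - 1L,
    end = GenomicRanges::end(placements),
    strand = as.character(GenomicRanges::strand(placements)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read placements written by [writePlacements()]
#'
#' @param path Path to the TSV file.
#' @return A named GRanges of read placements.
#' @export
readPlacements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop("missing '#' header line in ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L][nzchar(lines[-1L])]
  if (!length(body)) {
    return(GenomicRanges::GRanges())
  }
  df <- read.table(text = body, sep = "\t", col.names = cols,
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$genome_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  names(gr) <- df$read_id
  gr
}

# ---------------------------------------------------------------------------
# Feature tables
# ---------------------------------------------------------------------------

#' Write a feature table as TSV
#'
#' One row per overlap candidate; missing feature values (e.g. an undefined
#' comparative score) are written as `NA`.
#'
#' @param tbl Feature data.frame with key columns `readA, readB,
#'   orientation`, numeric feature columns and optionally a `label` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(tbl, path) {
  tbl <- as.data.frame(tbl)
  if (!all(c("readA", "readB", "orientation") %in% names(tbl)))
    stop("feature table needs readA/readB/orientation key columns",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tbl), collapse = "\t")), con)
  if (nrow(tbl))
    write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatures()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per overlap candidate.
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop("missing '#' header line in ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L][nzchar(lines[-1L])]
  if (!length(body)) {
    tbl <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(tbl)
  }
  df <- read.table(text = body, sep = "\t", col.names = cols, na.strings = "NA",
                   stringsAsFactors = FALSE)
  df
}

# ---------------------------------------------------------------------------
# Model persistence
# ---------------------------------------------------------------------------

MODEL_MAGIC <- "OverlapCorrectModel"
MODEL_VERSION <- 1L

#' Save a trained overlap classifier
#'
#' The file carries a magic header and a format version so stale or foreign
#' files are rejected on load.
#'
#' @param model An [OverlapClassifier-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  if (!methods::is(model, "OverlapClassifier"))
    stop("model must be an OverlapClassifier", call. = FALSE)
  saveRDS(list(magic = MODEL_MAGIC, version = MODEL_VERSION, model = model),
          path)
  invisible(path)
}

#' Load a classifier saved by [saveModel()]
#'
#' @param path Path to the model file.
#' @return The [OverlapClassifier-class] object.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt model file: ", path,
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$magic, MODEL_MAGIC))
    stop("corrupt model file (bad magic): ", path, call. = FALSE)
  if (!identical(obj$version, MODEL_VERSION))
    stop("model file version mismatch: ", obj$version, call. = FALSE)
  obj$model
}
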