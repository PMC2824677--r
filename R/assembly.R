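# Minimal unitig-style contigger: containment removal, transitive
# reduction, maximal non-branching paths, majority-vote consensus; plus
# reference-relative assembly evaluation (N50, percent genome matched).

#' Filter overlap candidates by predicted labels
#'
#' Keeps exactly the candidates predicted `true`, preserving order.
#'
#' @param candidates Overlap table.
#' @param predictions Label vector (`"true"`/`"false"`), one per row.
#' @return The retained candidate rows.
#' @export
filterOverlaps <- function(candidates, predictions) {
  candidates <- as.data.frame(candidates)
  p <- as_label_factor(predictions)
  if (length(p) != nrow(candidates))
    stop("one prediction per candidate required (got ", length(p),
         " for ", nrow(candidates), " candidates)", call. = FALSE)
  keep <- p == "true"
  if (!any(keep) && nrow(candidates))
    warning("all candidates predicted false; empty overlap set retained")
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")
node_id <- function(read, strand) paste0(read, "/", strand)

# Directed oriented edges from canonical dovetail rows (containments were
# removed upstream, so a_hang and b_hang share a strict sign).  Each row
# yields the walk edge and its reverse-complement mirror.  An oriented
# node (read, '+') is the read as stored; a '+' edge target keeps the
# target's stored orientation, a '-' target reads it reverse-complemented.
directed_edges <- function(tbl) {
  if (!nrow(tbl)) {
    return(data.frame(from_read = character(0), from_strand = character(0),
                      to_read = character(0), to_strand = character(0),
                      offset = integer(0), ext = integer(0),
                      pair = integer(0)))
  }
  d <- ifelse(tbl$orientation == "same", "+", "-")
  fwd <- tbl$a_hang > 0  # readA leads the layout; otherwise oriented B does
  n <- nrow(tbl)
  data.frame(
    from_read = c(ifelse(fwd, tbl$readA, tbl$readB),
                  ifelse(fwd, tbl$readB, tbl$readA)),
    from_strand = c(ifelse(fwd, "+", d),
                    ifelse(fwd, flip_strand(d), "-")),
    to_read = c(ifelse(fwd, tbl$readB, tbl$readA),
                ifelse(fwd, tbl$readA, tbl$readB)),
    to_strand = c(ifelse(fwd, d, "+"),
                  ifelse(fwd, "-", flip_strand(d))),
    offset = c(ifelse(fwd, tbl$a_hang, -tbl$a_hang),
               ifelse(fwd, tbl$b_hang, -tbl$b_hang)),
    # ext: bases the target read extends past the source read's end --
    # exact in the target's base coordinates (it is the mirror's offset)
    ext = c(ifelse(fwd, tbl$b_hang, -tbl$b_hang),
            ifelse(fwd, tbl$a_hang, -tbl$a_hang)),
    pair = rep(seq_len(n), 2L),
    stringsAsFactors = FALSE)
}

#' Build the overlap graph
#'
#' Contained reads (one read's aligned region spanning the whole other
#' read) are recorded and removed; the remaining dovetail overlaps become
#' directed edges between oriented reads, and transitive edges (implied by
#' two shorter edges within `slack` bp) are removed.
#'
#' @param reads Named DNAStringSet.
#' @param candidates Retained overlap table (canonical form).
#' @param slack Offset slack for transitive reduction (bp).
#' @return A list with `nodes` (kept read ids), `edges` (directed edge
#'   table with mirrors), and `containment` (named character: contained
#'   read -> container).
#' @export
buildOverlapGraph <- function(reads, candidates, slack = 10L) {
  check_reads(reads)
  tbl <- as.data.frame(candidates)
  unknown <- setdiff(unique(c(tbl$readA, tbl$readB)), names(reads))
  if (length(unknown))
    stop("candidates reference unknown reads: ",
         paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
  if (any(tbl$readA == tbl$readB))
    stop("self-overlap in candidate table", call. = FALSE)
  # containment: B in A when a_hang >= 0 & b_hang <= 0; A in B mirrored
  containment <- character(0)
  if (nrow(tbl)) {
    b_in_a <- tbl$a_hang >= 0 & tbl$b_hang <= 0
    a_in_b <- tbl$a_hang <= 0 & tbl$b_hang >= 0 & !b_in_a
    contained <- c(tbl$readB[b_in_a], tbl$readA[a_in_b])
    container <- c(tbl$readA[b_in_a], tbl$readB[a_in_b])
    keep1 <- !duplicated(contained)
    containment <- setNames(container[keep1], contained[keep1])
    # a container that is itself contained points onward; resolve one level
    drop <- names(containment)
    tbl <- tbl[!(tbl$readA %in% drop | tbl$readB %in% drop), , drop = FALSE]
  }
  nodes <- setdiff(names(reads), names(containment))
  edges <- directed_edges(tbl)
  # transitive reduction
  if (nrow(edges)) {
    ekey <- paste(node_id(edges$from_read, edges$from_strand),
                  node_id(edges$to_read, edges$to_strand), sep = " ")
    eoff <- setNames(edges$offset, ekey)
    by_from <- split(seq_len(nrow(edges)),
                     node_id(edges$from_read, edges$from_strand))
    drop_pair <- logical(max(edges$pair))
    for (idx in by_from) {
      if (length(idx) < 2L) next
      idx <- idx[order(edges$offset[idx])]
      tgt <- node_id(edges$to_read[idx], edges$to_strand[idx])
      off <- edges$offset[idx]
      for (q in seq_along(idx)[-1L]) {
        for (p in seq_len(q - 1L)) {
          key <- paste(tgt[p], tgt[q], sep = " ")
          off3 <- eoff[key]
          if (!is.na(off3) && abs(off[p] + off3 - off[q]) <= slack) {
            drop_pair[edges$pair[idx[q]]] <- TRUE
            break
          }
        }
      }
    }
    edges <- edges[!drop_pair[edges$pair], , drop = FALSE]
  }
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, containment = containment)
}

#' Build contigs from a reduced overlap graph
#'
#' Reads whose oriented nodes all have in- and out-degree at most one are
#' chained into maximal simple paths; reads incident to a branch join no
#' path and, like isolated reads, become single-read contigs.  The
#' consensus is a per-column majority vote over the layout (ties broken
#' alphabetically).
#'
#' @param graph Output of [buildOverlapGraph()].
#' @param reads Named DNAStringSet.
#' @return A list with `contigs` (named DNAStringSet) and `layout` (list
#'   of data.frames with `read, offset, strand` per contig).
#' @export
buildContigs <- function(graph, reads) {
  check_reads(reads)
  nodes <- graph$nodes
  edges <- graph$edges
  if (!length(nodes))
    return(list(contigs = Biostrings::DNAStringSet(), layout = list()))
  outdeg <- table(node_id(edges$from_read, edges$from_strand))
  branch_reads <- unique(edges$from_read[
    node_id(edges$from_read, edges$from_strand) %in%
      names(outdeg)[outdeg > 1L]])
  ok_edge <- !(edges$from_read %in% branch_reads) &
    !(edges$to_read %in% branch_reads)
  e <- edges[ok_edge, , drop = FALSE]
  nxt <- setNames(seq_len(nrow(e)), node_id(e$from_read, e$from_strand))
  has_pred <- unique(node_id(e$to_read, e$to_strand))
  used <- character(0)
  paths <- list()
  chain_reads <- setdiff(nodes, branch_reads)
  # path starts: oriented nodes with no predecessor
  for (r in chain_reads) {
    for (s in c("+", "-")) {
      v <- node_id(r, s)
      if (v %in% has_pred) next
      if (r %in% used) next
      # walk; offsets are exact draft coordinates (the spliced draft grows
      # by each edge's ext, the target's unaligned suffix length)
      path_read <- r; path_strand <- s; path_off <- 0L
      dl <- Biostrings::width(reads[r])
      cur <- v
      repeat {
        ei <- nxt[cur]
        if (is.na(ei)) break
        tr <- e$to_read[ei]; ts <- e$to_strand[ei]
        if (tr %in% path_read || tr %in% used) break
        dl <- dl + e$ext[ei]
        path_read <- c(path_read, tr)
        path_strand <- c(path_strand, ts)
        path_off <- c(path_off, dl - Biostrings::width(reads[tr]))
        cur <- node_id(tr, ts)
      }
      if (length(path_read) > 1L || !(v %in% names(nxt))) {
        used <- c(used, path_read)
        paths[[length(paths) + 1L]] <-
          data.frame(read = path_read, offset = path_off,
                     strand = path_strand, stringsAsFactors = FALSE)
      }
    }
  }
  # anything left over (isolated or branch reads) becomes a singleton
  for (r in setdiff(nodes, used)) {
    paths[[length(paths) + 1L]] <-
      data.frame(read = r, offset = 0L, strand = "+",
                 stringsAsFactors = FALSE)
  }
  contigs <- vapply(paths, function(p) consensus_sequence(p, reads), "")
  cset <- Biostrings::DNAStringSet(contigs)
  names(cset) <- sprintf("contig%05d", seq_along(paths))
  names(paths) <- names(cset)
  list(contigs = cset, layout = paths)
}

# Majority-vote consensus over a layout.  A draft is spliced from the
# reads at their layout offsets, every read is realigned to its draft
# window with a banded fitting alignment, and each draft column takes the
# majority base over the aligned reads (ties alphabetical; a column whose
# majority vote is a deletion is dropped).
consensus_sequence <- function(layout, reads, band = 16L) {
  seqs <- as.character(reads[layout$read])
  rev <- layout$strand == "-"
  seqs[rev] <- rc_chr(seqs[rev])
  if (length(seqs) == 1L) return(seqs)
  lens <- nchar(seqs)
  draft <- seqs[1L]
  for (i in seq_along(seqs)[-1L]) {
    dl <- nchar(draft)
    off <- layout$offset[i]
    if (off > dl) {
      draft <- paste0(draft, strrep("N", off - dl), seqs[i])
    } else if (off + lens[i] > dl) {
      draft <- paste0(draft, substr(seqs[i], dl - off + 1L, lens[i]))
    }
  }
  cpp_consensus(draft, seqs, as.integer(layout$offset), as.integer(band))
}

#' Reference-relative N50
#'
#' The shortest contig length at which the lengths of all contigs at least
#' that long sum to half the reference length; 0 when the assembly never
#' reaches half.
#'
#' @param lengths Contig lengths (bp), or an [AssemblyReport-class].
#' @param referenceLength Reference genome length (bp).
#' @return N50 in bp.
#' @export
setGeneric("n50", function(lengths, referenceLength) standardGeneric("n50"))

#' @rdname n50
#' @export
setMethod("n50", "numeric", function(lengths, referenceLength) {
  if (any(lengths < 0)) stop("negative contig length", call. = FALSE)
  if (referenceLength <= 0) stop("referenceLength must be > 0", call. = FALSE)
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  hit <- which(cum >= referenceLength / 2)
  if (!length(hit)) return(0)
  s[hit[1L]]
})

#' Percent of the reference genome matched by contigs
#'
#' Contigs are cut into windows which are mapped to the reference on both
#' strands (local alignments of at least `minMatch` bp at `minIdentity`);
#' the fraction of reference positions covered by at least one alignment
#' is reported, counted once.
#'
#' @param contigs Named DNAStringSet of contigs.
#' @param reference Length-1 named DNAStringSet.
#' @param minMatch Minimum aligned length (bp).
#' @param minIdentity Minimum alignment identity.
#' @param chunk Window size used to localise contig-to-reference
#'   alignments (bp).
#' @return Percentage in \[0, 100\].
#' @export
pctGenomeMatched <- function(contigs, reference, minMatch = 100L,
                             minIdentity = 0.95, chunk = 500L) {
  stopifnot(methods::is(reference, "DNAStringSet"), length(reference) == 1L)
  refLen <- Biostrings::width(reference)[1L]
  pieces <- chunk_contigs(contigs, chunk, minMatch)
  if (!length(pieces)) return(0)
  hits <- mapReadToGenome(pieces, reference, mersize = 16L,
                          minIdentity = minIdentity, minCoverage = 0.5,
                          band = max(32L, chunk %/% 10L))
  if (!length(hits)) return(0)
  keep <- hits$columns >= minMatch
  if (!any(keep)) return(0)
  cov <- IRanges::reduce(IRanges::ranges(hits[keep]))
  cov <- IRanges::restrict(cov, start = 1L, end = refLen)
  100 * sum(IRanges::width(cov)) / refLen
}

chunk_contigs <- function(contigs, chunk, minMatch) {
  out <- character(0)
  nms <- character(0)
  for (i in seq_along(contigs)) {
    s <- as.character(contigs[[i]])
    len <- nchar(s)
    if (len < minMatch) next
    starts <- seq(1L, max(1L, len - minMatch + 1L), by = chunk)
    ends <- pmin(starts + chunk - 1L, len)
    # merge a trailing sliver into the previous window
    if (length(starts) > 1L && ends[length(ends)] - starts[length(starts)] +
        1L < minMatch) {
      starts <- starts[-length(starts)]
      ends[length(ends) - 1L] <- len
      ends <- ends[-length(ends)]
    }
    out <- c(out, substring(s, starts, ends))
    nms <- c(nms, sprintf("%s.w%04d", names(contigs)[i], seq_along(starts)))
  }
  if (!length(out)) return(Biostrings::DNAStringSet())
  x <- Biostrings::DNAStringSet(out)
  names(x) <- nms
  x
}

#' AssemblyReport
#'
#' Contigs plus reference-relative summary statistics.
#'
#' @slot contigs Contig consensus sequences.
#' @slot layout Per-contig layout (read, offset, strand).
#' @slot n50 Reference-relative N50 (bp).
#' @slot pctMatched Percent of the reference matched by contigs.
#' @slot misassemblies Number of contigs with non-colinear reference
#'   alignments.
#' @slot referenceLength Reference length (bp).
#' @aliases AssemblyReport
#' @exportClass AssemblyReport
setClass("AssemblyReport",
         representation(contigs = "ANY", layout = "list", n50 = "numeric",
                        pctMatched = "numeric", misassemblies = "integer",
                        referenceLength = "numeric"))

setValidity("AssemblyReport", function(object) {
  if (object@pctMatched < 0 || object@pctMatched > 100)
    return("pctMatched must be in [0, 100]")
  lens <- Biostrings::width(object@contigs)
  if (length(lens) && object@n50 != 0 && !(object@n50 %in% lens))
    return("n50 must be one of the contig lengths or 0")
  TRUE
})

setMethod("show", "AssemblyReport", function(object) {
  cat("AssemblyReport\n")
  cat(sprintf("  contigs: %d (total %d bp)\n", length(object@contigs),
              sum(Biostrings::width(object@contigs))))
  cat(sprintf("  N50 (reference-relative): %.0f bp\n", object@n50))
  cat(sprintf("  %% genome matched: %.2f\n", object@pctMatched))
  cat(sprintf("  flagged misassemblies: %d\n", object@misassemblies))
})

#' @rdname n50
#' @export
setMethod("n50", c("AssemblyReport", "missing"),
          function(lengths, referenceLength) lengths@n50)

#' Accessors for assembly reports
#'
#' @param report An [AssemblyReport-class].
#' @return `contigSequences`: the contig DNAStringSet; `contigLengths`:
#'   integer contig lengths (bp); `pctMatched`: percent of the reference
#'   matched.
#' @export
contigSequences <- function(report) report@contigs

#' @rdname contigSequences
#' @export
pctMatched <- function(report) report@pctMatched

#' @rdname contigSequences
#' @export
contigLengths <- function(report) Biostrings::width(report@contigs)

#' Assemble reads and evaluate against a reference
#'
#' Runs [buildOverlapGraph()] and [buildContigs()] on the retained
#' candidates and scores the contigs against the reference.
#'
#' @param reads Named DNAStringSet.
#' @param candidates Retained overlap table.
#' @param reference Length-1 named DNAStringSet used for evaluation.
#' @param minMatch,minIdentity,chunk Passed to [pctGenomeMatched()].
#' @param slack Transitive-reduction slack (bp).
#' @return An [AssemblyReport-class].
#' @export
evaluateAssembly <- function(reads, candidates, reference, minMatch = 100L,
                             minIdentity = 0.95, chunk = 500L, slack = 10L) {
  graph <- buildOverlapGraph(reads, candidates, slack = slack)
  asm <- buildContigs(graph, reads)
  refLen <- Biostrings::width(reference)[1L]
  lens <- Biostrings::width(asm$contigs)
  mis <- count_misassemblies(asm$contigs, reference, chunk, minMatch)
  methods::new("AssemblyReport", contigs = asm$contigs, layout = asm$layout,
               n50 = as.numeric(n50(as.numeric(lens), refLen)),
               pctMatched = pctGenomeMatched(asm$contigs, reference,
                                             minMatch, minIdentity, chunk),
               misassemblies = mis, referenceLength = as.numeric(refLen))
}

# A contig is flagged when the reference placements of its windows are not
# colinear (strand flip or a jump far from the window spacing).
count_misassemblies <- function(contigs, reference, chunk = 500L,
                                minMatch = 100L, jump = 2000L) {
  flags <- 0L
  for (i in seq_along(contigs)) {
    pieces <- chunk_contigs(contigs[i], chunk, minMatch)
    if (length(pieces) < 2L) next
    hits <- mapReadToGenome(pieces, reference, mersize = 16L,
                            minIdentity = 0.9, minCoverage = 0.5,
                            band = max(32L, chunk %/% 10L))
    if (length(hits) < 2L) next
    hdf <- data.frame(id = hits$read_id,
                      start = GenomicRanges::start(hits),
                      strand = as.character(GenomicRanges::strand(hits)),
                      matches = hits$matching_bases)
    hdf <- hdf[order(hdf$id, -hdf$matches), ]
    hdf <- hdf[!duplicated(hdf$id), ]
    hdf <- hdf[order(hdf$id), ]
    if (nrow(hdf) < 2L) next
    dstart <- abs(diff(hdf$start))
    if (any(hdf$strand != hdf$strand[1L]) || any(dstart > chunk + jump))
      flags <- flags + 1L
  }
  flags
}
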