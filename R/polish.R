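## Stage 5: alignment-based residual-error polishing. Error-corrected reads
## are aligned to each unitig; alignments with large indels or low identity
## are removed (so short alternatively spliced exons are not averaged away),
## and the survivors drive a per-column pileup consensus.

#' Align reads to a single target sequence
#'
#' Overlap-mode dynamic-programming alignment of each read against the
#' target, in both orientations (the better one is reported). Reads sharing
#' too few 15-mers with the target are skipped cheaply.
#'
#' @param reads named character vector.
#' @param target a single target sequence.
#' @param minSharedKmers prescreen threshold (default 8).
#' @return data.frame with \code{query_id}, \code{query_len},
#'   \code{query_start}, \code{query_end}, \code{strand},
#'   \code{target_start}, \code{target_end}, \code{matching_bases},
#'   \code{block_len}, \code{identity}, \code{largest_indel}.
#' @export
alignReadsTo <- function(reads, target, minSharedKmers = 8L) {
    reads <- .as_seqs(reads)
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    .align_batch_cpp(names(reads), unname(reads), as.character(target),
                     as.integer(minSharedKmers))
}

#' Filter read-to-unitig alignments for polishing
#'
#' Keeps exactly the alignments whose largest indel is at most
#' \code{maxIndel} nt and whose identity is at least \code{minIdentity}.
#' The indel gate prevents reads from a different isoform, whose alignment
#' spans a skipped exon as one long deletion, from voting that exon out of
#' the unitig.
#'
#' @param alignments data.frame from \code{\link{alignReadsTo}} with
#'   \code{identity} and \code{largest_indel} columns.
#' @param maxIndel largest tolerated indel in nt (default 50).
#' @param minIdentity minimum alignment identity (default 0.70).
#' @return the filtered data.frame.
#' @export
filterPolishAlignments <- function(alignments, maxIndel = 50L,
                                   minIdentity = 0.70) {
    keep <- alignments$largest_indel <= maxIndel &
        alignments$identity >= minIdentity
    alignments[keep, , drop = FALSE]
}

#' Polish one sequence by pileup consensus
#'
#' Per-column weighted majority over the aligned read bases, including
#' deletion votes; any tie (including a 2-vs-2 split) keeps the draft base,
#' and columns without read coverage keep the draft base. Insertions are
#' accepted when supported by more than half of the reads covering the
#' junction. The output length may therefore differ from the input.
#'
#' @param unitig draft sequence.
#' @param alignments filtered alignments of reads to this unitig
#'   (\code{\link{filterPolishAlignments}}).
#' @param readSeqs named character vector holding the read sequences.
#' @return polished sequence.
#' @export
polishSequence <- function(unitig, alignments, readSeqs) {
    if (is.null(alignments) || nrow(alignments) == 0L)
        return(as.character(unitig))
    readSeqs <- .as_seqs(readSeqs)
    oriented <- character(nrow(alignments))
    for (i in seq_len(nrow(alignments))) {
        s <- readSeqs[[alignments$query_id[i]]]
        oriented[i] <- if (alignments$strand[i] == "-") revComp(s) else s
    }
    .polish_cpp(as.character(unitig), oriented)
}

#' Polish a set of unitigs with error-corrected reads
#'
#' Convenience wrapper running \code{\link{alignReadsTo}},
#' \code{\link{filterPolishAlignments}} and \code{\link{polishSequence}} per
#' unitig.
#'
#' @param unitigs named character vector of draft unitigs.
#' @param reads named character vector of error-corrected reads.
#' @param maxIndel,minIdentity alignment filter gates (defaults 50 nt, 0.70).
#' @return list with \code{unitigs} (polished, same names) and
#'   \code{alignments} (list of per-unitig filtered alignment data.frames).
#' @export
polishUnitigs <- function(unitigs, reads, maxIndel = 50L, minIdentity = 0.70) {
    unitigs <- .as_seqs(unitigs)
    reads <- .as_seqs(reads)
    out <- unitigs
    alns <- vector("list", length(unitigs))
    names(alns) <- names(unitigs)
    for (u in names(unitigs)) {
        a <- alignReadsTo(reads, unitigs[[u]])
        a <- filterPolishAlignments(a, maxIndel, minIdentity)
        alns[[u]] <- a
        out[[u]] <- polishSequence(unitigs[[u]], a, reads)
    }
    list(unitigs = out, alignments = alns)
}
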