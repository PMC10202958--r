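## All-vs-all overlap detection (internal minimizer-chain overlapper) plus
## PAF import/export so an external overlapper can be substituted.

#' Find all-vs-all overlaps among sequences
#'
#' Overlaps are seeded with canonical minimizers, chained along diagonals,
#' and extended exactly at both ends. Dovetail, containment and internal
#' overlaps at least \code{minOverlap} nt long are reported once per pair in
#' canonical id order; with \code{stranded = TRUE} minus-strand hits are
#' suppressed.
#'
#' @param seqs named character vector (unique names) or
#'   \code{\link{readFastx}} data.frame.
#' @param minOverlap minimum overlap length in nt (default 150).
#' @param stranded suppress minus-strand overlaps?
#' @param k,w minimizer k-mer length and window (defaults 15 and 10).
#' @param maxGap maximum diagonal drift within a chain in nt (default 100).
#' @param minAnchors minimum chained minimizers per overlap (default 3).
#' @return data.frame of overlap records with PAF-like columns:
#'   \code{query_id}, \code{query_len}, \code{query_start}, \code{query_end},
#'   \code{strand}, \code{target_id}, \code{target_len}, \code{target_start},
#'   \code{target_end}, \code{matching_bases}, \code{block_len},
#'   \code{identity} (all coordinates 0-based half-open, target coordinates
#'   on the target's forward strand).
#' @export
findReadOverlaps <- function(seqs, minOverlap = 150L, stranded = FALSE,
                             k = 15L, w = 10L, maxGap = 100L,
                             minAnchors = 3L) {
    seqs <- .as_seqs(seqs)
    if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
    if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
    if (length(seqs) == 0L) stop("no sequences supplied")
    .find_overlaps_cpp(names(seqs), unname(seqs), as.integer(minOverlap),
                       stranded, as.integer(k), as.integer(w),
                       as.integer(maxGap), as.integer(minAnchors), 500L)
}

#' Classify overlap records by overhang geometry
#'
#' Standard string-graph classification from the unaligned overhangs at the
#' four sequence ends (computed in the query's orientation):
#' \code{CONTAINED} (query inside target), \code{CONTAINS},
#' \code{DOVETAIL_QT} (query suffix to target prefix), \code{DOVETAIL_TQ},
#' or \code{INTERNAL}.
#'
#' @param overlaps overlap record data.frame (see
#'   \code{\link{findReadOverlaps}}).
#' @param maxOverhang tolerated unaligned overhang in nt (default 25).
#' @return the input with a \code{type} column appended.
#' @export
classifyOverlaps <- function(overlaps, maxOverhang = 25L) {
    if (nrow(overlaps) == 0L) {
        overlaps$type <- character(0)
        return(overlaps)
    }
    qh <- overlaps$query_start
    qt <- overlaps$query_len - overlaps$query_end
    plus <- overlaps$strand == "+"
    th <- ifelse(plus, overlaps$target_start,
                 overlaps$target_len - overlaps$target_end)
    tt <- ifelse(plus, overlaps$target_len - overlaps$target_end,
                 overlaps$target_start)
    o <- maxOverhang
    type <- rep("INTERNAL", nrow(overlaps))
    type[qt <= o & th <= o] <- "DOVETAIL_QT"
    type[qh <= o & tt <= o] <- "DOVETAIL_TQ"
    contq <- qh <= o & qt <= o
    contt <- th <= o & tt <= o
    type[contt] <- "CONTAINS"
    type[contq] <- "CONTAINED"
    type[contq & contt] <- ifelse(
        overlaps$query_len[contq & contt] <= overlaps$target_len[contq & contt],
        "CONTAINED", "CONTAINS")
    overlaps$type <- type
    overlaps
}

#' Write overlap records as PAF
#'
#' Emits the 12 mandatory tab-separated PAF columns (mapping quality written
#' as 255) plus any optional tags preserved in a \code{tags} column.
#'
#' @param overlaps overlap record data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePAF <- function(overlaps, path) {
    lines <- character(nrow(overlaps))
    for (i in seq_len(max(0L, nrow(overlaps)))) {
        fields <- c(overlaps$query_id[i], overlaps$query_len[i],
                    overlaps$query_start[i], overlaps$query_end[i],
                    overlaps$strand[i], overlaps$target_id[i],
                    overlaps$target_len[i], overlaps$target_start[i],
                    overlaps$target_end[i], overlaps$matching_bases[i],
                    overlaps$block_len[i], 255L)
        if (!is.null(overlaps$tags) && nzchar(overlaps$tags[i]))
            fields <- c(fields, overlaps$tags[i])
        lines[i] <- paste(fields, collapse = "\t")
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a PAF file into overlap records
#'
#' @param path PAF file (12+ mandatory columns; optional tags are preserved
#'   verbatim in a \code{tags} column).
#' @return overlap record data.frame; \code{identity} is estimated as
#'   \code{matching_bases / block_len}.
#' @export
readPAF <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    empty <- data.frame(query_id = character(), query_len = integer(),
                        query_start = integer(), query_end = integer(),
                        strand = character(), target_id = character(),
                        target_len = integer(), target_start = integer(),
                        target_end = integer(), matching_bases = integer(),
                        block_len = integer(), identity = numeric(),
                        tags = character(), stringsAsFactors = FALSE)
    if (length(lines) == 0L) return(empty)
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 12L)
            stop(sprintf("malformed PAF line %d: expected 12+ columns, got %d",
                         i, length(f)))
        num <- suppressWarnings(as.integer(f[c(2:4, 7:11)]))
        if (anyNA(num) || !(f[5] %in% c("+", "-")))
            stop(sprintf("malformed PAF line %d", i))
        rows[[i]] <- data.frame(
            query_id = f[1], query_len = num[1], query_start = num[2],
            query_end = num[3], strand = f[5], target_id = f[6],
            target_len = num[4], target_start = num[5], target_end = num[6],
            matching_bases = num[7], block_len = num[8],
            identity = num[7] / num[8],
            tags = if (length(f) > 12L)
                       paste(f[13:length(f)], collapse = "\t") else "",
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}
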