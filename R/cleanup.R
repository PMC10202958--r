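## Stage 3: depth-based trimming and chimera splitting. A region of a read
## is sufficiently covered when it overlaps at least two other reads (depth
## >= 3 counting the read itself); insufficiently covered heads/tails are
## trimmed and internal valleys -- the signature of chimeric fusions --
## split the read.

#' Per-base depth profile of a read
#'
#' Depth is self-inclusive: position \eqn{i} has depth 1 plus the number of
#' overlap records whose aligned interval on this read covers \eqn{i}.
#' All overlap types (dovetail, containment, internal) contribute, but only
#' over their aligned interval, so chimeric junctions show up as depth
#' valleys.
#'
#' @param readId read identifier.
#' @param readLength read length in nt.
#' @param overlaps overlap records involving this read as query or target.
#' @return integer vector of length \code{readLength}.
#' @export
computeDepthProfile <- function(readId, readLength, overlaps) {
    delta <- integer(readLength + 1L)
    add <- function(s, e) {
        if (anyNA(c(s, e)) || s < 0 || e > readLength || s >= e)
            stop("overlap coordinates out of range for read ", readId)
        delta[s + 1L] <<- delta[s + 1L] + 1L
        delta[e + 1L] <<- delta[e + 1L] - 1L
    }
    if (nrow(overlaps)) {
        asQ <- overlaps$query_id == readId
        asT <- overlaps$target_id == readId
        for (i in which(asQ)) add(overlaps$query_start[i], overlaps$query_end[i])
        for (i in which(asT)) add(overlaps$target_start[i], overlaps$target_end[i])
    }
    1L + cumsum(delta[seq_len(readLength)])
}

#' Trim and split reads by coverage depth
#'
#' Computes all-vs-all overlaps among the reads (unless supplied), removes
#' reads completely contained in another read, and for each remaining read
#' emits the maximal runs with depth at least \code{minDepth} as segments,
#' discarding runs shorter than \code{minSegment}. Segment ids are suffixed
#' \code{_p0}, \code{_p1}, ... with original coordinates recorded. Overlaps
#' contributed by contained reads still count towards the depth of the
#' reads that contain them.
#'
#' @param reads named character vector (or \code{\link{readFastx}}
#'   data.frame).
#' @param overlaps optional precomputed overlap records; computed with
#'   \code{\link{findReadOverlaps}} otherwise.
#' @param minDepth minimum read depth (default 3: the read itself plus at
#'   least two others).
#' @param minSegment minimum emitted segment length in nt (default 200).
#' @param stranded passed to \code{\link{findReadOverlaps}}.
#' @param minOverlap passed to \code{\link{findReadOverlaps}}.
#' @param junctionMargin before profiling, overlap intervals are shrunk by
#'   this many nt at any end that is interior to the profiled read (default
#'   3). Alignments ending inside a read abut a chimeric junction to within
#'   a few by-chance matching bases, so without the margin a well-supported
#'   junction would appear spanned; ends at the read boundary are left
#'   untouched.
#' @return list with \code{segments} (named character vector) and \code{log}
#'   (data.frame: \code{read_id}, \code{segment_id}, \code{start},
#'   \code{end}; removed reads have \code{NA} segment).
#' @export
trimSplitReads <- function(reads, overlaps = NULL, minDepth = 3L,
                           minSegment = 200L, stranded = FALSE,
                           minOverlap = 150L, junctionMargin = 3L) {
    seqs <- .as_seqs(reads)
    if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
    if (length(seqs) == 0L)
        return(list(segments = character(),
                    log = data.frame(read_id = character(),
                                     segment_id = character(),
                                     start = integer(), end = integer())))
    if (is.null(overlaps))
        overlaps <- findReadOverlaps(seqs, minOverlap = minOverlap,
                                     stranded = stranded)
    overlaps <- classifyOverlaps(overlaps)
    contained <- unique(c(
        overlaps$query_id[overlaps$type == "CONTAINED"],
        overlaps$target_id[overlaps$type == "CONTAINS"]))
    segs <- character()
    logRows <- list()
    for (id in names(seqs)) {
        if (id %in% contained) {
            logRows[[length(logRows) + 1L]] <-
                data.frame(read_id = id, segment_id = NA_character_,
                           start = NA_integer_, end = NA_integer_,
                           stringsAsFactors = FALSE)
            next
        }
        len <- nchar(seqs[[id]])
        rel <- overlaps[overlaps$query_id == id | overlaps$target_id == id, ,
                        drop = FALSE]
        if (nrow(rel) && junctionMargin > 0L) {
            m <- junctionMargin
            asQ <- rel$query_id == id
            rel$query_start[asQ] <- ifelse(rel$query_start[asQ] > 0L,
                                           rel$query_start[asQ] + m,
                                           rel$query_start[asQ])
            rel$query_end[asQ] <- ifelse(rel$query_end[asQ] < len,
                                         rel$query_end[asQ] - m,
                                         rel$query_end[asQ])
            asT <- rel$target_id == id
            rel$target_start[asT] <- ifelse(rel$target_start[asT] > 0L,
                                            rel$target_start[asT] + m,
                                            rel$target_start[asT])
            rel$target_end[asT] <- ifelse(rel$target_end[asT] < len,
                                          rel$target_end[asT] - m,
                                          rel$target_end[asT])
            ok <- (!asQ | rel$query_start < rel$query_end) &
                  (!asT | rel$target_start < rel$target_end)
            rel <- rel[ok, , drop = FALSE]
        }
        depth <- computeDepthProfile(id, len, rel)
        ok <- depth >= minDepth
        r <- rle(ok)
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        pi <- 0L
        for (j in seq_along(r$values)) {
            if (!r$values[j] || r$lengths[j] < minSegment) next
            sid <- if (r$lengths[j] == len) id
                   else sprintf("%s_p%d", id, pi)
            segs[sid] <- substr(seqs[[id]], s[j], e[j])
            logRows[[length(logRows) + 1L]] <-
                data.frame(read_id = id, segment_id = sid,
                           start = s[j] - 1L, end = e[j],
                           stringsAsFactors = FALSE)
            pi <- pi + 1L
        }
    }
    list(segments = segs,
         log = if (length(logRows)) do.call(rbind, logRows)
               else data.frame(read_id = character(),
                               segment_id = character(),
                               start = integer(), end = integer()))
}
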