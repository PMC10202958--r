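## Stage 6: transcript extraction from the polished-unitig overlap graph.
## Vertices carry length-normalized read counts, edges carry the number of
## reads spanning the overlap; a binomial test prunes under-supported edges
## (false overlaps between transcripts of different expression magnitude),
## poly(A) read alignments fix unitig orientations in cDNA mode, and
## transcripts are extracted by count-ordered bidirectional greedy extension.

#' Build an overlap graph of polished unitigs
#'
#' Runs the internal overlapper on the unitigs, classifies the records, and
#' keeps dovetail edges.
#'
#' @param unitigs named character vector of polished unitigs.
#' @param stranded logical.
#' @param minOverlap minimum overlap in nt (default 150).
#' @return an \linkS4class{OverlapGraph}.
#' @export
buildUnitigGraph <- function(unitigs, stranded = FALSE, minOverlap = 150L) {
    unitigs <- .as_seqs(unitigs)
    ov <- if (length(unitigs) > 1L)
        classifyOverlaps(findReadOverlaps(unitigs, minOverlap = minOverlap,
                                          stranded = stranded))
    else
        classifyOverlaps(data.frame(
            query_id = character(), query_len = integer(),
            query_start = integer(), query_end = integer(),
            strand = character(), target_id = character(),
            target_len = integer(), target_start = integer(),
            target_end = integer(), matching_bases = integer(),
            block_len = integer(), identity = numeric(),
            stringsAsFactors = FALSE))
    buildOverlapGraph(ov, unitigs, stranded = stranded)
}

#' Length-normalized read count of a unitig
#'
#' The number of read bases aligned to the unitig divided by the unitig
#' length. A read aligning partially to two unitigs contributes to each in
#' proportion to its aligned bases, which keeps reads spanning unitig
#' overlaps from being double-counted.
#'
#' @param alignments filtered read alignments to this unitig
#'   (\code{\link{alignReadsTo}} rows; target coordinates on the unitig).
#' @param unitigLength unitig length in nt (> 0).
#' @return numeric count.
#' @export
normalizedReadCount <- function(alignments, unitigLength) {
    if (unitigLength <= 0) stop("zero-length unitig")
    if (is.null(alignments) || nrow(alignments) == 0L) return(0)
    sum(alignments$target_end - alignments$target_start) / unitigLength
}

#' Annotate a unitig graph with counts and edge support
#'
#' @param graph an \linkS4class{OverlapGraph} of unitigs.
#' @param alignments named list (per unitig) of filtered read alignments, as
#'   returned by \code{\link{polishUnitigs}}.
#' @param unitigLengths named integer vector of unitig lengths.
#' @return the graph with a \code{count} column on vertices and a
#'   \code{support} column on edges (reads aligned to both incident
#'   unitigs).
#' @export
annotateUnitigGraph <- function(graph, alignments, unitigLengths) {
    counts <- vapply(graph@vertices$id, function(id)
        normalizedReadCount(alignments[[id]], unitigLengths[[id]]),
        numeric(1))
    graph@vertices$count <- unname(counts)
    e <- graph@edges
    if (nrow(e)) {
        idOf <- setNames(graph@vertices$id, graph@vertices$vid)
        readsOf <- lapply(alignments, function(a)
            if (is.null(a)) character() else unique(a$query_id))
        e$support <- vapply(seq_len(nrow(e)), function(i)
            length(intersect(readsOf[[idOf[[e$from[i]]]]],
                             readsOf[[idOf[[e$to[i]]]]])), integer(1))
    } else {
        e$support <- integer(0)
    }
    graph@edges <- e
    graph
}

#' Binomial test filter on unitig-overlap edges
#'
#' For an edge with spanning-read support \eqn{s} between unitigs with
#' normalized counts \eqn{c_u, c_v}, let \eqn{n = round(min(c_u, c_v))}.
#' The edge is removed when the one-sided exact binomial probability
#' \eqn{P(X \le s \mid n, p)} falls below \code{alpha}: far fewer reads span
#' the junction than the expression of the less-expressed unitig predicts,
#' the signature of a false overlap. Edges with \eqn{n < 3} are kept
#' (insufficient evidence either way).
#'
#' @param graph an annotated \linkS4class{OverlapGraph}
#'   (\code{\link{annotateUnitigGraph}}).
#' @param alpha significance level (default 0.05).
#' @param spanningProb success probability \eqn{p} of a read spanning the
#'   junction (default 0.5).
#' @param minEvidence evidence floor on \eqn{n} (default 3).
#' @return the graph with failing edges removed.
#' @export
binomialEdgeFilter <- function(graph, alpha = 0.05, spanningProb = 0.5,
                               minEvidence = 3L) {
    e <- graph@edges
    if (nrow(e) == 0L) return(graph)
    cnt <- setNames(graph@vertices$count, graph@vertices$vid)
    n <- round(pmin(cnt[e$from], cnt[e$to]))
    p <- pbinom(pmin(e$support, n), n, spanningProb)
    drop <- n >= minEvidence & p < alpha
    graph@edges <- e[!drop, , drop = FALSE]
    rownames(graph@edges) <- NULL
    graph
}

#' Reorient unitigs by poly(A) read alignments and collapse the graph
#'
#' Each unitig with at least one aligned poly(A)/poly(T) read is assigned
#' the orientation that places poly(A) tails at its 3' end. Votes are
#' restricted to signal-bearing reads whose alignment covers most of the
#' read (partial cross-alignments through a shared region carry no
#' orientation information) and weighted by aligned bases; conflicts are
#' resolved by the weighted majority and logged as an attribute. Unitigs
#' without evidence keep their forward orientation. The strand-symmetric
#' graph is then collapsed to one vertex per unitig, dropping every edge
#' inconsistent with the assigned orientations -- in particular the
#' head-to-head junctions between antisense overlapping genes -- and, as in
#' the unitig-assembly stage, 3'-extending edges out of tail-evidenced
#' unitigs are pruned: nothing genuine extends beyond a poly(A) tail.
#'
#' @param graph an unstranded, annotated \linkS4class{OverlapGraph} of
#'   unitigs.
#' @param signals poly(A) signals of the reads
#'   (\code{\link{detectPolyASignals}}).
#' @param alignments named list (per unitig) of filtered read alignments.
#' @return a collapsed \linkS4class{OverlapGraph} with one vertex per unitig.
#' @export
reorientByPolyA <- function(graph, signals, alignments) {
    prefOf <- setNames(ifelse(signals$kind == "TAIL_A", "+",
                       ifelse(signals$kind == "HEAD_T", "-", NA_character_)),
                       signals$read_id)
    ids <- unique(graph@vertices$id)
    orientOf <- setNames(rep("+", length(ids)), ids)
    hasTail <- setNames(rep(FALSE, length(ids)), ids)
    conflicts <- character()
    for (id in ids) {
        a <- alignments[[id]]
        if (is.null(a) || nrow(a) == 0L) next
        pr <- prefOf[a$query_id]
        readCover <- (a$query_end - a$query_start) / a$query_len
        keep <- !is.na(pr) & readCover >= 0.8
        if (!any(keep)) next
        implied <- ifelse(pr[keep] == "+", a$strand[keep],
                          .flip(a$strand[keep]))
        w <- (a$target_end - a$target_start)[keep]
        wFwd <- sum(w[implied == "+"])
        wRev <- sum(w[implied == "-"])
        if (wFwd > 0 && wRev > 0) conflicts <- c(conflicts, id)
        orientOf[id] <- if (wRev > wFwd) "-" else "+"
        hasTail[id] <- TRUE
    }
    v <- graph@vertices
    keepV <- v$orient == orientOf[v$id]
    v2 <- v[keepV, , drop = FALSE]
    e <- graph@edges
    keepE <- e$from %in% v2$vid & e$to %in% v2$vid &
        !hasTail[sub(".$", "", e$from)]   # no 3' extension past a tail
    g <- new("OverlapGraph", vertices = v2, edges = e[keepE, , drop = FALSE],
             stranded = TRUE)
    g@vertices$pref <- ifelse(hasTail[g@vertices$id], g@vertices$orient,
                              NA_character_)
    attr(g, "orientConflicts") <- conflicts
    g
}

#' Greedy expression-guided transcript extraction
#'
#' Vertices are sorted by read count in descending order (ties broken by
#' longer unitig, then id) and serve as seeds for bidirectional greedy
#' extension: each step moves to the neighbor with the highest current read
#' count, terminating at a dead end, a cycle (a vertex already on the path),
#' or a zero-count vertex. The path is spliced into a transcript, every
#' vertex on it is flagged from seeding further paths (though it may still
#' be traversed, as shared exons require), and the counts along the path are
#' decremented by the path minimum. Seeds whose count has dropped to zero
#' are flagged without emission. Extraction ends when all vertices have been
#' flagged.
#'
#' @param graph a filtered, oriented, annotated \linkS4class{OverlapGraph}
#'   (one vertex per unitig, \code{count} column present).
#' @param seqs named character vector of unitig sequences (forward
#'   orientation).
#' @return list with \code{transcripts} (named character vector) and
#'   \code{info} (data.frame: \code{transcript_id}, \code{path},
#'   \code{min_count}).
#' @export
greedyAssembleTranscripts <- function(graph, seqs) {
    seqs <- .as_seqs(seqs)
    v <- graph@vertices
    e <- graph@edges
    count <- setNames(as.numeric(v$count), v$vid)
    len <- setNames(v$len, v$vid)
    outN <- split(e$to, e$from)
    inN <- split(e$from, e$to)
    edgeKey <- paste(e$from, e$to, sep = "\r")

    seeds <- v$vid[order(-v$count, -v$len, v$vid)]
    flagged <- setNames(logical(nrow(v)), v$vid)
    transcripts <- character()
    info <- list()

    bestNeighbor <- function(cands, path) {
        cands <- setdiff(cands, path)        # cycle rule: never revisit
        if (length(cands) == 0L) return(NA_character_)
        cands <- cands[order(-count[cands], cands)]
        if (count[cands[1L]] <= 0) return(NA_character_)
        cands[1L]
    }

    spliceTranscript <- function(path) {
        s <- .orientedSeq(path[1L], graph, seqs)
        if (length(path) > 1L) for (i in seq_len(length(path) - 1L)) {
            ei <- match(paste(path[i], path[i + 1L], sep = "\r"), edgeKey)
            rec <- e[ei, ]
            off <- nchar(s) - len[[path[i]]]
            nxt <- .orientedSeq(path[i + 1L], graph, seqs)
            s <- paste0(substr(s, 1L, off + rec$from_end),
                        substr(nxt, rec$to_end + 1L, nchar(nxt)))
        }
        s
    }

    for (seed in seeds) {
        if (flagged[seed]) next
        path <- seed
        repeat {                              # extend right (3')
            nxt <- bestNeighbor(outN[[path[length(path)]]], path)
            if (is.na(nxt)) break
            path <- c(path, nxt)
        }
        repeat {                              # extend left (5')
            prv <- bestNeighbor(inN[[path[1L]]], path)
            if (is.na(prv)) break
            path <- c(prv, path)
        }
        minCount <- min(count[path])
        if (count[seed] > 0 && minCount > 0) {
            id <- sprintf("txp%06d", length(transcripts) + 1L)
            transcripts[id] <- spliceTranscript(path)
            info[[length(info) + 1L]] <- data.frame(
                transcript_id = id, path = paste(path, collapse = ","),
                min_count = minCount, stringsAsFactors = FALSE)
            count[path] <- count[path] - minCount
        }
        flagged[path] <- TRUE
    }
    list(transcripts = transcripts,
         info = if (length(info)) do.call(rbind, info)
                else data.frame(transcript_id = character(),
                                path = character(), min_count = numeric()))
}
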