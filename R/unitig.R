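## Stage 4: overlap-graph construction, poly(A)/poly(T) strand pruning,
## Myers-style transitive reduction, and unambiguous-path unitig assembly.

#' OverlapGraph class
#'
#' A string graph of oriented sequences. In unstranded (cDNA) mode every
#' sequence contributes two vertices, one per orientation, and every edge has
#' a mirror edge, so the graph is strand-symmetric until poly(A) pruning. An
#' edge \code{u -> v} means the suffix of \code{u}'s oriented sequence
#' overlaps the prefix of \code{v}'s; its coordinates record the aligned
#' interval on both oriented sequences.
#'
#' @slot vertices data.frame: \code{vid} (oriented id), \code{id},
#'   \code{orient} (\code{+}/\code{-}), \code{len}, \code{pref} (preferred
#'   orientation from a poly(A) signal, or \code{NA}).
#' @slot edges data.frame: \code{from}, \code{to}, \code{from_start},
#'   \code{from_end}, \code{to_start}, \code{to_end}, \code{olen}.
#' @slot stranded logical.
#' @export
setClass("OverlapGraph", representation(vertices = "data.frame",
                                        edges = "data.frame",
                                        stranded = "logical"),
         validity = function(object) {
             e <- object@edges
             if (nrow(e) && any(e$from == e$to)) return("self-loop edge")
             TRUE
         })

setMethod("show", "OverlapGraph", function(object) {
    cat(sprintf("OverlapGraph (%s): %d vertices, %d edges\n",
                if (object@stranded) "stranded" else "unstranded",
                nrow(object@vertices), nrow(object@edges)))
})

#' @rdname OverlapGraph-class
#' @param graph an \linkS4class{OverlapGraph}.
#' @export
graphVertices <- function(graph) graph@vertices

#' @rdname OverlapGraph-class
#' @export
graphEdges <- function(graph) graph@edges

.flip <- function(o) ifelse(o == "+", "-", "+")

## interval (s, e) on the forward strand expressed in `orient` coordinates
.orientInterval <- function(s, e, len, orient) {
    if (orient == "+") c(s, e) else c(len - e, len - s)
}

#' Detect a poly(A) tail or poly(T) head
#'
#' Scans the terminal \code{window} nt of the read: a \code{TAIL_A} signal is
#' the longest read suffix within the window containing at least
#' \code{minTail} A's at purity \code{minPurity} or better; \code{HEAD_T} is
#' the symmetric test for T at the 5' end. \code{TAIL_A} takes precedence
#' when both are present. The reported \code{tail_length} is the number of
#' signal bases in the qualifying stretch.
#'
#' @param read a single read sequence.
#' @param minTail minimum signal bases (default 10).
#' @param window terminal window scanned in nt (default 20).
#' @param minPurity minimum fraction of signal bases (default 0.9).
#' @return list with \code{kind} (\code{"TAIL_A"}, \code{"HEAD_T"} or
#'   \code{"NONE"}) and \code{tail_length}.
#' @export
detectPolyA <- function(read, minTail = 10L, window = 20L, minPurity = 0.9) {
    n <- nchar(read)
    scan <- function(chars, base) {
        best <- 0L
        hits <- cumsum(chars == base)
        for (l in seq_along(chars)) {
            if (hits[l] >= minTail && hits[l] / l >= minPurity)
                best <- hits[l]
        }
        best
    }
    w <- min(window, n)
    tailChars <- rev(strsplit(substr(read, n - w + 1L, n), "")[[1L]])
    headChars <- strsplit(substr(read, 1L, w), "")[[1L]]
    aLen <- scan(tailChars, "A")
    tLen <- scan(headChars, "T")
    if (aLen >= minTail) list(kind = "TAIL_A", tail_length = aLen)
    else if (tLen >= minTail) list(kind = "HEAD_T", tail_length = tLen)
    else list(kind = "NONE", tail_length = 0L)
}

#' @rdname detectPolyA
#' @param reads named character vector.
#' @param ... passed to \code{detectPolyA}.
#' @return for \code{detectPolyASignals}, a data.frame with \code{read_id},
#'   \code{kind}, \code{tail_length}.
#' @export
detectPolyASignals <- function(reads, ...) {
    reads <- .as_seqs(reads)
    res <- lapply(reads, detectPolyA, ...)
    data.frame(read_id = names(reads),
               kind = vapply(res, `[[`, character(1), "kind"),
               tail_length = vapply(res, `[[`, integer(1), "tail_length"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an overlap graph from classified overlap records
#'
#' Only dovetail overlaps become edges. In stranded mode only plus-strand
#' records are used and each sequence has a single (forward) vertex; in
#' unstranded mode both orientations get vertices and every edge is added
#' together with its mirror, keeping the graph strand-symmetric.
#'
#' @param overlaps classified overlap records
#'   (\code{\link{classifyOverlaps}}); completely contained sequences should
#'   already have been removed.
#' @param seqs named character vector of the sequences (defines the vertex
#'   set, including overlap-free singletons).
#' @param stranded logical.
#' @return an \linkS4class{OverlapGraph}.
#' @export
buildOverlapGraph <- function(overlaps, seqs, stranded = FALSE) {
    seqs <- .as_seqs(seqs)
    ids <- names(seqs)
    lens <- nchar(seqs)
    orients <- if (stranded) "+" else c("+", "-")
    vertices <- data.frame(
        vid = paste0(rep(ids, each = length(orients)),
                     rep(orients, length(ids))),
        id = rep(ids, each = length(orients)),
        orient = rep(orients, length(ids)),
        len = rep(unname(lens), each = length(orients)),
        pref = NA_character_, stringsAsFactors = FALSE)
    edges <- list()
    addEdge <- function(fid, fo, fint, tid, to, tint, flen, tlen, olen) {
        if (fid == tid) return(invisible())
        edges[[length(edges) + 1L]] <<- data.frame(
            from = paste0(fid, fo), to = paste0(tid, to),
            from_start = fint[1], from_end = fint[2],
            to_start = tint[1], to_end = tint[2], olen = olen,
            stringsAsFactors = FALSE)
        if (!stranded) {
            edges[[length(edges) + 1L]] <<- data.frame(
                from = paste0(tid, .flip(to)), to = paste0(fid, .flip(fo)),
                from_start = tlen - tint[2], from_end = tlen - tint[1],
                to_start = flen - fint[2], to_end = flen - fint[1],
                olen = olen, stringsAsFactors = FALSE)
        }
    }
    ov <- overlaps[overlaps$type %in% c("DOVETAIL_QT", "DOVETAIL_TQ") &
                   overlaps$query_id %in% ids &
                   overlaps$target_id %in% ids, , drop = FALSE]
    if (stranded) ov <- ov[ov$strand == "+", , drop = FALSE]
    for (i in seq_len(nrow(ov))) {
        qid <- ov$query_id[i]; tid <- ov$target_id[i]
        qlen <- ov$query_len[i]; tlen <- ov$target_len[i]
        tor <- ov$strand[i]
        tint <- .orientInterval(ov$target_start[i], ov$target_end[i], tlen, tor)
        qint <- c(ov$query_start[i], ov$query_end[i])
        olen <- min(qint[2] - qint[1], tint[2] - tint[1])
        if (ov$type[i] == "DOVETAIL_QT")
            addEdge(qid, "+", qint, tid, tor, tint, qlen, tlen, olen)
        else
            addEdge(tid, tor, tint, qid, "+", qint, tlen, qlen, olen)
    }
    edges <- if (length(edges)) do.call(rbind, edges)
             else data.frame(from = character(), to = character(),
                             from_start = integer(), from_end = integer(),
                             to_start = integer(), to_end = integer(),
                             olen = integer(), stringsAsFactors = FALSE)
    if (nrow(edges)) {
        ## deduplicate parallel edges, keeping the longest overlap
        edges <- edges[order(edges$from, edges$to, -edges$olen), , drop = FALSE]
        edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
        bad <- !(edges$from %in% vertices$vid) | !(edges$to %in% vertices$vid)
        if (any(bad)) {
            warning(sum(bad), " edge(s) referencing removed vertices skipped")
            edges <- edges[!bad, , drop = FALSE]
        }
        edges <- edges[edges$from != edges$to, , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("OverlapGraph", vertices = vertices, edges = edges,
        stranded = stranded)
}

#' Prune an overlap graph with poly(A)/poly(T) signals
#'
#' Each signal-bearing read has a preferred orientation: the one that places
#' its poly(A) tail at the 3' end (\code{TAIL_A} reads prefer \code{+},
#' \code{HEAD_T} reads prefer \code{-}). Nothing genuine extends beyond a
#' poly(A) tail, so a vertex in its preferred orientation loses its outgoing
#' edges and, symmetrically, a vertex in its anti-preferred orientation
#' (poly(T) head at the 5' end) loses its incoming edges. Edges joining two
#' signal-bearing reads that cannot be realized with both reads in their
#' preferred orientations -- the head-to-head geometry of antisense
#' overlapping genes -- are removed as well.
#'
#' @param graph an \linkS4class{OverlapGraph}.
#' @param signals data.frame from \code{\link{detectPolyASignals}}.
#' @return the pruned graph (preferred orientations recorded on vertices).
#' @export
pruneByPolyA <- function(graph, signals) {
    pref <- setNames(rep(NA_character_, nrow(graph@vertices)),
                     graph@vertices$vid)
    if (!is.null(signals) && nrow(signals)) {
        prefOf <- setNames(ifelse(signals$kind == "TAIL_A", "+",
                            ifelse(signals$kind == "HEAD_T", "-",
                                   NA_character_)),
                           signals$read_id)
        graph@vertices$pref <- unname(prefOf[graph@vertices$id])
        pref <- setNames(graph@vertices$pref, graph@vertices$vid)
    }
    e <- graph@edges
    if (nrow(e) == 0L) return(graph)
    vOrient <- setNames(graph@vertices$orient, graph@vertices$vid)
    vPref <- setNames(graph@vertices$pref, graph@vertices$vid)
    fromPref <- vPref[e$from]; toPref <- vPref[e$to]
    fromOr <- vOrient[e$from]; toOr <- vOrient[e$to]
    drop <- (!is.na(fromPref) & fromOr == fromPref) |
            (!is.na(toPref) & toOr == .flip(toPref)) |
            (!is.na(fromPref) & !is.na(toPref))
    graph@edges <- e[!drop, , drop = FALSE]
    rownames(graph@edges) <- NULL
    graph
}

## novel bases an edge's target adds beyond the overlap
.edgeExt <- function(graph) {
    vLen <- setNames(graph@vertices$len, graph@vertices$vid)
    unname(vLen[graph@edges$to]) - graph@edges$to_end
}

#' Transitive reduction of an overlap graph
#'
#' Myers-style string-graph reduction: an edge \code{u -> w} is removed when
#' edges \code{u -> v} and \code{v -> w} exist whose combined extension
#' length matches that of \code{u -> w} within \code{fuzz} nt. The vertex
#' set is unchanged and reachability is preserved.
#'
#' @param graph an \linkS4class{OverlapGraph}.
#' @param fuzz coordinate tolerance in nt (default 10), absorbing residual
#'   indels in the overlap coordinates.
#' @return the reduced graph.
#' @export
transitiveReduce <- function(graph, fuzz = 10L) {
    e <- graph@edges
    if (nrow(e) < 2L) return(graph)
    ext <- .edgeExt(graph)
    key <- paste(e$from, e$to, sep = "\r")
    extOf <- setNames(ext, key)
    outIdx <- split(seq_len(nrow(e)), e$from)
    eliminated <- logical(nrow(e))
    for (u in names(outIdx)) {
        idx <- outIdx[[u]]
        if (length(idx) < 2L) next
        idx <- idx[order(ext[idx])]
        inplay <- setNames(idx, e$to[idx])
        for (ei in idx) {
            v <- e$to[ei]
            vIdx <- outIdx[[v]]
            if (is.null(vIdx)) next
            for (ej in vIdx[order(ext[vIdx])]) {
                w <- e$to[ej]
                wi <- inplay[w]
                if (is.na(wi) || w == u) next
                if (abs(ext[ei] + ext[ej] - extOf[[paste(u, w, sep = "\r")]])
                    <= fuzz)
                    eliminated[wi] <- TRUE
            }
        }
    }
    graph@edges <- e[!eliminated, , drop = FALSE]
    rownames(graph@edges) <- NULL
    graph
}

## oriented sequence of a vertex
.orientedSeq <- function(vid, graph, seqs) {
    v <- graph@vertices[match(vid, graph@vertices$vid), ]
    s <- seqs[[v$id]]
    if (v$orient == "-") revComp(s) else s
}

#' Assemble unitigs from a reduced overlap graph
#'
#' Maximal paths whose edges join a vertex of out-degree one to a vertex of
#' in-degree one are merged by splicing the overlap coordinates: the first
#' vertex contributes its full oriented sequence and each successor its
#' non-overlapping suffix. In unstranded mode each path has a mirror image
#' and is emitted once, in the canonical orientation (poly(A) tail at the
#' 3' end when a signal is recorded on the path, otherwise the
#' lexicographically smaller of the sequence and its reverse complement).
#'
#' @param graph a (reduced) \linkS4class{OverlapGraph}.
#' @param seqs named character vector of the vertex sequences (forward
#'   orientation).
#' @return list with \code{unitigs} (named character vector), \code{paths}
#'   (list of vertex-id vectors, parallel to \code{unitigs}).
#' @export
assembleUnitigs <- function(graph, seqs) {
    seqs <- .as_seqs(seqs)
    v <- graph@vertices
    e <- graph@edges
    outdeg <- table(factor(e$from, levels = v$vid))
    indeg <- table(factor(e$to, levels = v$vid))
    ## unitig edges: unambiguous extension in both directions
    uedge <- e[outdeg[e$from] == 1L & indeg[e$to] == 1L, , drop = FALSE]
    nextOf <- setNames(uedge$to, uedge$from)
    hasPrev <- v$vid %in% uedge$to
    starts <- v$vid[!hasPrev]
    visited <- setNames(logical(nrow(v)), v$vid)
    paths <- list()
    walk <- function(s) {
        p <- s
        visited[s] <<- TRUE
        while (!is.na(nxt <- nextOf[p[length(p)]]) && !visited[nxt]) {
            p <- c(p, unname(nxt))
            visited[nxt] <<- TRUE
        }
        p
    }
    for (s in starts) paths[[length(paths) + 1L]] <- walk(s)
    ## leftovers are cycles of unitig edges; break at the smallest vid
    while (any(!visited)) {
        s <- min(names(visited)[!visited])
        paths[[length(paths) + 1L]] <- walk(s)
    }

    edgeKey <- paste(e$from, e$to, sep = "\r")
    vPref <- setNames(v$pref, v$vid)
    vOrient <- setNames(v$orient, v$vid)
    vLen <- setNames(v$len, v$vid)

    spliceSeq <- function(p) {
        s <- .orientedSeq(p[1L], graph, seqs)
        if (length(p) > 1L) for (i in seq_len(length(p) - 1L)) {
            ei <- match(paste(p[i], p[i + 1L], sep = "\r"), edgeKey)
            rec <- e[ei, ]
            off <- nchar(s) - vLen[[p[i]]]
            toLen <- vLen[[p[i + 1L]]]
            if (rec$to_end >= toLen) {
                warning("inconsistent overlap coordinates; path broken")
                return(list(seq = s, p = p[seq_len(i)]))
            }
            nxtSeq <- .orientedSeq(p[i + 1L], graph, seqs)
            s <- paste0(substr(s, 1L, off + rec$from_end),
                        substr(nxtSeq, rec$to_end + 1L, toLen))
        }
        list(seq = s, p = p)
    }

    unitigs <- character()
    outPaths <- list()
    seen <- character()
    for (p in paths) {
        if (!graph@stranded) {
            mirror <- rev(paste0(substr(p, 1L, nchar(p) - 1L),
                                 .flip(substring(p, nchar(p)))))
            keyA <- paste(p, collapse = ";")
            keyB <- paste(mirror, collapse = ";")
            if (min(keyA, keyB) %in% seen) next
            seen <- c(seen, min(keyA, keyB))
            sp <- spliceSeq(p)
            ## canonical orientation: poly(A) evidence, else lexicographic
            scoreFwd <- sum(vPref[sp$p] == vOrient[sp$p], na.rm = TRUE)
            scoreRev <- sum(vPref[sp$p] == .flip(vOrient[sp$p]), na.rm = TRUE)
            sq <- sp$seq
            if (scoreRev > scoreFwd ||
                (scoreRev == scoreFwd && revComp(sq) < sq))
                sq <- revComp(sq)
            unitigs <- c(unitigs, sq)
            outPaths[[length(outPaths) + 1L]] <- sp$p
        } else {
            sp <- spliceSeq(p)
            unitigs <- c(unitigs, sp$seq)
            outPaths[[length(outPaths) + 1L]] <- sp$p
        }
    }
    names(unitigs) <- sprintf("utg%06d", seq_along(unitigs))
    names(outPaths) <- names(unitigs)
    list(unitigs = unitigs, paths = outPaths)
}

#' Export an overlap graph as GFA1
#'
#' Writes S lines for the forward sequences and L lines for the dovetail
#' edges (overlap length as a CIGAR match).
#'
#' @param graph an \linkS4class{OverlapGraph}.
#' @param seqs named character vector of vertex sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGFA <- function(graph, seqs, path) {
    seqs <- .as_seqs(seqs)
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines("H\tVN:Z:1.0", con)
    for (id in unique(graph@vertices$id))
        writeLines(paste("S", id, seqs[[id]], sep = "\t"), con)
    e <- graph@edges
    for (i in seq_len(nrow(e))) {
        fo <- substring(e$from[i], nchar(e$from[i]))
        to <- substring(e$to[i], nchar(e$to[i]))
        writeLines(paste("L", substr(e$from[i], 1L, nchar(e$from[i]) - 1L), fo,
                         substr(e$to[i], 1L, nchar(e$to[i]) - 1L), to,
                         paste0(e$olen[i], "M"), sep = "\t"), con)
    }
    invisible(path)
}
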