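## Stage 1: alignment-free error correction. Reads are split into fixed-
## length tiles; within each tile a dynamic multiplicity threshold separates
## weak (likely erroneous) from solid k-mers, and anchored runs of weak
## k-mers are replaced by an alternative solid path in the de Bruijn graph
## when that path aligns to the original span at high identity. The pass is
## repeated with half-shifted tiles so errors straddling tile boundaries get
## a second chance.

#' Error-correction parameters
#'
#' @param k k-mer length (default 25).
#' @param tileLength tile length in nt (default 500); must exceed \code{k}.
#' @param minPathIdentity minimum global-alignment identity between a
#'   candidate replacement path and the original span (default 0.70).
#' @param maxIterations maximum tiling passes; iteration 1 tiles from offset
#'   0, iteration 2 from half a tile length, alternating. Passes repeat
#'   while edits are still being made; the read is a fixed point once both
#'   tiling offsets pass cleanly (default 12).
#' @param minSolidFractionKeep reads whose fraction of solid k-mers after
#'   correction falls below this are discarded (default 0.1).
#' @param maxStates bounded search budget (states expanded) per weak run.
#' @return validated parameter list of class \code{CorrectionConfig}.
#' @export
correctionParams <- function(k = 25L, tileLength = 500L,
                             minPathIdentity = 0.70, maxIterations = 12L,
                             minSolidFractionKeep = 0.1, maxStates = 64L) {
    stopifnot(minPathIdentity > 0, minPathIdentity <= 1, tileLength > k,
              maxIterations >= 1, minSolidFractionKeep >= 0, k >= 2, k <= 32)
    structure(list(k = as.integer(k), tileLength = as.integer(tileLength),
                   minPathIdentity = minPathIdentity,
                   maxIterations = as.integer(maxIterations),
                   minSolidFractionKeep = minSolidFractionKeep,
                   maxStates = as.integer(maxStates)),
              class = "CorrectionConfig")
}

#' Tile a read into fixed-length windows
#'
#' Tiles cover \code{[offset, readLength)} contiguously without overlap; the
#' last tile may be short, and a non-zero offset emits a leading tile
#' \code{[0, offset)}.
#'
#' @param readLength read length in nt (> 0).
#' @param tileLength tile length in nt.
#' @param offset 0 or half a tile length.
#' @return data.frame with 0-based half-open \code{start}, \code{end}.
#' @examples
#' tileRead(1200, 500, 0)    # (0,500) (500,1000) (1000,1200)
#' tileRead(1200, 500, 250)  # (0,250) (250,750) (750,1200)
#' @export
tileRead <- function(readLength, tileLength, offset = 0L) {
    if (readLength <= 0) stop("readLength must be positive")
    if (offset >= readLength)
        return(data.frame(start = 0L, end = as.integer(readLength)))
    starts <- unique(c(if (offset > 0) 0L,
                       seq.int(offset, readLength - 1L, by = tileLength)))
    ends <- pmin(c(starts[-1L], starts[length(starts)] + tileLength),
                 readLength)
    data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Dynamic weak/solid multiplicity threshold for one tile
#'
#' Returns \eqn{t \ge 2} such that k-mers with multiplicity below \eqn{t} are
#' labelled weak and those at or above it solid. The base rule is
#' \code{t = max(2, ceiling(q25/10))} with \code{q25} the 25th percentile of
#' the tile's multiplicities, accounting for tile-local expression level;
#' it is then refined to the deepest valley of the multiplicity histogram
#' below the tile median when such a valley exists, which separates the
#' error mode (multiplicity ~1) from the coverage mode on high-coverage
#' tiles.
#'
#' @param multiplicities integer vector of k-mer multiplicities within one
#'   tile (non-negative; invalid k-mers coded -1 are ignored).
#' @return integer threshold \eqn{\ge 2}.
#' @export
dynamicThreshold <- function(multiplicities) {
    m <- multiplicities[multiplicities >= 0]
    if (length(m) == 0L) return(2L)
    t0 <- max(2L, as.integer(ceiling(quantile(m, 0.25, names = FALSE) / 10)))
    med <- median(m)
    if (med > 2) {
        ## histogram over 1..floor(med); a valley is a less-populated
        ## multiplicity value right above a populated bin. Only valleys that
        ## separate an error-like low mode are eligible: the modal
        ## multiplicity below the valley must be <= 2, so that a valley
        ## between two genuine coverage modes (e.g. two isoforms sharing a
        ## tile) never reclassifies the minor mode as weak.
        counts <- tabulate(m + 1L, nbins = as.integer(floor(med)) + 1L)
        vals <- 2:as.integer(floor(med))
        if (length(vals) > 0) {
            cnt <- counts[vals + 1L]
            lo <- counts[vals]          # bin immediately below
            okLow <- vapply(vals, function(v) {
                below <- counts[seq_len(v)]     # multiplicities 0..v-1
                sum(below) > 0 && (which.max(below) - 1L) <= 2L
            }, logical(1))
            cand <- cnt < lo & okLow
            if (any(cand)) {
                valley <- vals[which(cand & cnt == min(cnt[cand]))][1L]
                t0 <- max(2L, as.integer(valley))
            }
        }
    }
    t0
}

## identity of two short spans via global unit-cost alignment
.editIdentity <- function(a, b) {
    n <- max(nchar(a), nchar(b))
    if (n == 0L) return(1)
    1 - .edit_distance_cpp(a, b) / n
}

#' Correct one tile of a read
#'
#' Maximal runs of weak k-mers flanked on both sides by solid anchor k-mers
#' are candidates for replacement: a bounded best-first search in the de
#' Bruijn graph looks for solid paths between the anchors (length cap
#' \code{1.5 x span + k}), and the best candidate replaces the span only if
#' its global-alignment identity against the original span is at least
#' \code{minPathIdentity}. Unanchored runs at the segment ends are left
#' unedited. Ties between equal-identity candidates are broken by higher
#' minimum multiplicity, then lexicographically.
#'
#' @param segment tile sequence.
#' @param graph a \linkS4class{KmerGraph}.
#' @param config a \code{\link{correctionParams}} list.
#' @param threshold optional multiplicity threshold; computed with
#'   \code{\link{dynamicThreshold}} when missing.
#' @return list with \code{seq} (possibly edited segment) and \code{modified}
#'   (logical).
#' @export
correctTile <- function(segment, graph, config = correctionParams(),
                        threshold = NULL) {
    k <- graph@k
    if (nchar(segment) < k + 2L)
        return(list(seq = segment, modified = FALSE))
    counts <- .kg_read_counts(graph@ptr, segment)
    if (is.null(threshold)) threshold <- dynamicThreshold(counts)
    solid <- counts >= threshold & counts >= 0
    if (all(solid) || !any(solid))
        return(list(seq = segment, modified = FALSE))
    r <- rle(solid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    modified <- FALSE
    ## process weak runs right-to-left so earlier coordinates stay valid
    for (i in rev(seq_along(r$values))) {
        if (r$values[i]) next
        if (i == 1L || i == length(r$values)) next  # unanchored at an end
        leftAnchor <- ends[i - 1L]       # 1-based k-mer index of solid anchor
        rightAnchor <- starts[i + 1L]
        ## replacement span: first base of left anchor .. last base of right
        spanStart <- leftAnchor
        spanEnd <- rightAnchor + k - 1L
        orig <- substr(segment, spanStart, spanEnd)
        maxLen <- as.integer(ceiling(nchar(orig) * 1.5 + k))
        cand <- .kg_find_paths(graph@ptr,
                               substr(segment, leftAnchor, leftAnchor + k - 1L),
                               substr(segment, rightAnchor, rightAnchor + k - 1L),
                               maxLen, as.integer(threshold),
                               config$maxStates, 8L)
        if (length(cand$seq) == 0L) next
        ident <- vapply(cand$seq, .editIdentity, numeric(1), b = orig,
                        USE.NAMES = FALSE)
        keep <- ident >= config$minPathIdentity
        if (!any(keep)) next
        ord <- order(-ident[keep], -cand$minmult[keep], cand$seq[keep])
        best <- cand$seq[keep][ord[1L]]
        if (best == orig) next
        segment <- paste0(substr(segment, 1L, spanStart - 1L), best,
                          substr(segment, spanEnd + 1L, nchar(segment)))
        modified <- TRUE
    }
    list(seq = segment, modified = modified)
}

#' Correct a single read
#'
#' Applies tiled correction for up to \code{maxIterations} passes, with the
#' tiling offset alternating between 0 and half a tile length, and stops
#' once two consecutive passes (one at each offset) modify nothing, so the
#' returned read is a fixed point of the procedure at both tilings. A read
#' whose fraction of solid k-mers
#' (multiplicity \eqn{\ge} 2) after correction is below
#' \code{minSolidFractionKeep} is discarded, as is any read shorter than k.
#'
#' @param read a single read sequence.
#' @param graph a \linkS4class{KmerGraph} built from the input reads.
#' @param config a \code{\link{correctionParams}} list.
#' @return list with \code{seq} (corrected sequence or \code{NA} if
#'   discarded), \code{discarded}, \code{reason}, \code{iterations}.
#' @export
correctRead <- function(read, graph, config = correctionParams()) {
    k <- graph@k
    if (nchar(read) < k)
        return(list(seq = NA_character_, discarded = TRUE,
                    reason = "shorter_than_k", iterations = 0L))
    seq <- as.character(read)
    iters <- 0L
    prevClean <- FALSE
    for (it in seq_len(config$maxIterations)) {
        offset <- if (it %% 2L == 1L) 0L else config$tileLength %/% 2L
        tiles <- tileRead(nchar(seq), config$tileLength, offset)
        pieces <- character(nrow(tiles))
        anyMod <- FALSE
        for (ti in seq_len(nrow(tiles))) {
            seg <- substr(seq, tiles$start[ti] + 1L, tiles$end[ti])
            res <- correctTile(seg, graph, config)
            pieces[ti] <- res$seq
            anyMod <- anyMod || res$modified
        }
        seq <- paste(pieces, collapse = "")
        iters <- it
        if (!anyMod && (prevClean || it == 1L)) break
        prevClean <- !anyMod
    }
    counts <- .kg_read_counts(graph@ptr, seq)
    solidFrac <- if (length(counts)) mean(counts >= 2L) else 0
    if (solidFrac < config$minSolidFractionKeep)
        return(list(seq = NA_character_, discarded = TRUE,
                    reason = "low_solid_fraction", iterations = iters))
    list(seq = seq, discarded = FALSE, reason = NA_character_,
         iterations = iters)
}

#' Correct a set of reads
#'
#' Builds the k-mer graph (unless one is supplied) and corrects each read
#' with \code{\link{correctRead}}.
#'
#' @param reads named character vector or \code{\link{readFastx}} data.frame.
#' @param shortReads optional short reads ingested into the same graph to
#'   aid correction (hybrid mode).
#' @param config a \code{\link{correctionParams}} list.
#' @param canonical strand-collapsed k-mers (\code{TRUE} for cDNA input).
#' @param graph optional prebuilt \linkS4class{KmerGraph}.
#' @param seed hash seed for the graph.
#' @return list with \code{reads} (named character vector of corrected,
#'   retained reads) and \code{discarded} (data.frame: \code{read_id},
#'   \code{reason}).
#' @export
correctReads <- function(reads, shortReads = NULL,
                         config = correctionParams(), canonical = TRUE,
                         graph = NULL, seed = 1L) {
    seqs <- .as_seqs(reads)
    if (is.null(names(seqs)) || anyNA(names(seqs)))
        names(seqs) <- paste0("read", seq_along(seqs))
    if (is.null(graph))
        graph <- buildKmerGraph(seqs, shortReads = shortReads, k = config$k,
                                canonical = canonical, seed = seed)
    out <- vector("list", length(seqs))
    for (i in seq_along(seqs)) out[[i]] <- correctRead(seqs[[i]], graph, config)
    keep <- !vapply(out, `[[`, logical(1), "discarded")
    corrected <- vapply(out[keep], `[[`, character(1), "seq")
    names(corrected) <- names(seqs)[keep]
    discarded <- data.frame(
        read_id = names(seqs)[!keep],
        reason = vapply(out[!keep], `[[`, character(1), "reason"),
        stringsAsFactors = FALSE)
    list(reads = corrected, discarded = discarded, graph = graph)
}
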