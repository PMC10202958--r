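## End-to-end pipeline driver: stages 1-6 in order, with per-stage counts.

#' Run the full assembly pipeline
#'
#' Executes error correction, digital normalization, depth-based
#' trimming/splitting, unitig assembly, polishing, and transcript
#' extraction. The whole pipeline is a pure function of the input reads,
#' the options, and the seed.
#'
#' @param reads named character vector or \code{\link{readFastx}} data.frame
#'   of long reads.
#' @param stranded strand-specific (dRNA) input? Unstranded (cDNA) input
#'   engages canonical k-mers, two-orientation strobemers, and poly(A)
#'   strand resolution.
#' @param shortReads optional short reads to augment the k-mer graph.
#' @param correction \code{\link{correctionParams}}.
#' @param normalization \code{\link{normalizationParams}}.
#' @param strobes \code{\link{strobemerParams}}.
#' @param minDepth,minSegment trimming parameters (defaults 3, 200).
#' @param minOverlap minimum overlap in nt for all overlap steps (default
#'   150).
#' @param alpha,spanningProb binomial edge-filter parameters (defaults 0.05,
#'   0.5).
#' @param seed seed for the hashed data structures.
#' @return list with \code{transcripts} (named character vector),
#'   \code{transcriptInfo}, \code{unitigs}, \code{stageCounts} (named
#'   integer vector of sequences surviving each stage), and
#'   \code{intermediates} (corrected/normalized/trimmed sets and logs).
#' @export
runPipeline <- function(reads, stranded = FALSE, shortReads = NULL,
                        correction = correctionParams(),
                        normalization = normalizationParams(),
                        strobes = strobemerParams(),
                        minDepth = 3L, minSegment = 200L, minOverlap = 150L,
                        alpha = 0.05, spanningProb = 0.5, seed = 1L) {
    seqs <- .as_seqs(reads)
    if (length(seqs) == 0L) stop("stage correct: empty input read set")
    if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))

    ## stages 1-2 (correction feeds straight into normalization)
    cor <- correctReads(seqs, shortReads = shortReads, config = correction,
                        canonical = !stranded, seed = seed)
    if (length(cor$reads) == 0L)
        stop("stage correct: all reads were discarded")
    norm <- digitalNormalize(cor$reads, config = normalization,
                             params = strobes, stranded = stranded)

    ## stage 3
    trim <- trimSplitReads(norm$reads, minDepth = minDepth,
                           minSegment = minSegment, stranded = stranded,
                           minOverlap = minOverlap)
    segs <- trim$segments
    if (length(segs) == 0L)
        stop("stage trim: no read segments survived trimming")

    ## stage 4
    ov <- classifyOverlaps(findReadOverlaps(segs, minOverlap = minOverlap,
                                            stranded = stranded))
    contained <- unique(c(ov$query_id[ov$type == "CONTAINED"],
                          ov$target_id[ov$type == "CONTAINS"]))
    segs4 <- segs[setdiff(names(segs), contained)]
    signals <- detectPolyASignals(segs4)
    g <- buildOverlapGraph(ov, segs4, stranded = stranded)
    if (!stranded) g <- pruneByPolyA(g, signals)
    g <- transitiveReduce(g)
    un <- assembleUnitigs(g, segs4)

    ## stage 5
    pol <- polishUnitigs(un$unitigs, cor$reads)

    ## stage 6
    ug <- buildUnitigGraph(pol$unitigs, stranded = stranded,
                           minOverlap = minOverlap)
    draftLens <- setNames(nchar(un$unitigs), names(un$unitigs))
    ug <- annotateUnitigGraph(ug, pol$alignments, draftLens)
    if (!stranded) {
        readSignals <- detectPolyASignals(cor$reads)
        ug <- reorientByPolyA(ug, readSignals, pol$alignments)
    }
    ug <- binomialEdgeFilter(ug, alpha = alpha, spanningProb = spanningProb)
    tx <- greedyAssembleTranscripts(ug, pol$unitigs)

    list(transcripts = tx$transcripts, transcriptInfo = tx$info,
         unitigs = pol$unitigs,
         stageCounts = c(input = length(seqs),
                         corrected = length(cor$reads),
                         normalized = length(norm$reads),
                         trimmed = length(segs),
                         unitigs = length(un$unitigs),
                         transcripts = length(tx$transcripts)),
         intermediates = list(corrected = cor$reads,
                              discarded = cor$discarded,
                              normalizeLog = norm$log,
                              trimLog = trim$log,
                              overlapGraph = g,
                              unitigGraph = ug,
                              unitigPaths = un$paths))
}
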