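## Transcript-level assembly evaluation against a reference transcript set
## with a known truth subset: per-contig assignment, per-transcript
## reconstruction levels, and the recall/FDR/F1/redundancy summary.

#' Evaluation parameters
#'
#' @param minSegment minimum alignment segment length in nt (default 100).
#' @param minIdentity minimum alignment identity (default 0.95).
#' @param maxIndel indels at or above this length disqualify a segment and
#'   mark the contig as a large-indel (LI) call (default 70).
#' @param completeFraction fraction of a transcript's length that must be
#'   reconstructed for a "complete" call (default 0.95).
#' @return validated parameter list of class \code{EvalConfig}.
#' @export
evalParams <- function(minSegment = 100L, minIdentity = 0.95, maxIndel = 70L,
                       completeFraction = 0.95) {
    stopifnot(minSegment > 0, minIdentity > 0, minIdentity <= 1, maxIndel > 0,
              completeFraction > 0, completeFraction <= 1)
    structure(list(minSegment = as.integer(minSegment),
                   minIdentity = minIdentity, maxIndel = as.integer(maxIndel),
                   completeFraction = completeFraction),
              class = "EvalConfig")
}

#' EvalReport class
#'
#' Tallies and derived metrics of a transcript-level assembly evaluation.
#' \code{TP = complete + partial} (truth transcripts with any reconstruction),
#' \code{FD = FP + MA + LI + UC}, \code{recall} is the percentage of truth
#' transcripts reconstructed, \code{FDR = FD / (FD + TP)},
#' \code{F1 = TP / [TP + 0.5 (FD + FN)]}, and \code{redundancy} is the number
#' of TP-representing contigs per TP transcript.
#'
#' @slot counts named numeric vector: \code{complete}, \code{partial},
#'   \code{missing}, \code{TP}, \code{FP}, \code{MA_intra}, \code{MA_inter},
#'   \code{LI}, \code{UC}, \code{contigs_tp}.
#' @slot recall,FDR,F1,redundancy derived metrics.
#' @export
setClass("EvalReport", representation(counts = "numeric", recall = "numeric",
                                      FDR = "numeric", F1 = "numeric",
                                      redundancy = "numeric"))

setMethod("show", "EvalReport", function(object) {
    c <- object@counts
    cat("Transcript assembly evaluation\n")
    cat(sprintf("  complete: %d  partial: %d  missing (FN): %d\n",
                c[["complete"]], c[["partial"]], c[["missing"]]))
    cat(sprintf("  TP: %d  FP: %d  MA: %d (intra %d / inter %d)  LI: %d  UC: %d\n",
                c[["TP"]], c[["FP"]], c[["MA_intra"]] + c[["MA_inter"]],
                c[["MA_intra"]], c[["MA_inter"]], c[["LI"]], c[["UC"]]))
    cat(sprintf("  recall: %.1f%%  FDR: %.3f  F1: %.3f  redundancy: %.2f\n",
                object@recall, object@FDR, object@F1, object@redundancy))
})

#' Align contigs to a reference transcript set
#'
#' Overlap-mode alignment of every contig against every reference transcript
#' (both orientations; a shared-k-mer prescreen skips hopeless pairs).
#'
#' @param contigs named character vector of assembled sequences.
#' @param reference named character vector of reference transcripts.
#' @return data.frame of alignment records with a \code{transcript_id}
#'   column; \code{target_*} coordinates are on the transcript.
#' @export
alignToReference <- function(contigs, reference) {
    contigs <- .as_seqs(contigs)
    reference <- .as_seqs(reference)
    rows <- list()
    for (t in names(reference)) {
        a <- alignReadsTo(contigs, reference[[t]], minSharedKmers = 5L)
        if (nrow(a)) {
            a$transcript_id <- t
            a$transcript_len <- nchar(reference[[t]])
            rows[[length(rows) + 1L]] <- a
        }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(query_id = character(), query_len = integer(),
                    query_start = integer(), query_end = integer(),
                    strand = character(), target_start = integer(),
                    target_end = integer(), matching_bases = integer(),
                    block_len = integer(), identity = numeric(),
                    largest_indel = integer(), transcript_id = character(),
                    transcript_len = integer(), stringsAsFactors = FALSE)
}

#' Filter alignments and assign contigs to transcripts
#'
#' Alignment segments failing the length/identity/indel gates are dropped.
#' A contig whose surviving disjoint segments (on the contig) hit more than
#' one transcript is a misassembly, intragenic when all hit transcripts of
#' one gene and intergenic otherwise; ties between truth and non-truth
#' transcripts resolve to the truth set; a contig whose only credible
#' alignments carry an indel of \code{maxIndel} nt or more is a large-indel
#' call (LI); contigs with no credible alignment at all are unclassified
#' (UC).
#'
#' @param alignments data.frame from \code{\link{alignToReference}}.
#' @param truthIds character vector of truth-set transcript ids.
#' @param geneMap named character vector transcript -> gene (optional; when
#'   missing every misassembly is counted intergenic).
#' @param config an \code{\link{evalParams}} list.
#' @return data.frame: \code{contig_id}, \code{category} (\code{TP},
#'   \code{FP}, \code{MA_intra}, \code{MA_inter}, \code{LI}, \code{UC}),
#'   \code{transcript_id} (assigned transcript for TP/FP, \code{NA}
#'   otherwise).
#' @export
filterAndAssign <- function(alignments, truthIds, geneMap = NULL,
                            config = evalParams()) {
    contigs <- unique(alignments$query_id)
    res <- lapply(contigs, function(cid) {
        a <- alignments[alignments$query_id == cid, , drop = FALSE]
        segLen <- a$target_end - a$target_start
        credible <- segLen >= config$minSegment &
            a$identity >= config$minIdentity
        strict <- credible & a$largest_indel < config$maxIndel
        if (!any(strict)) {
            cat_ <- if (any(credible)) "LI" else "UC"
            return(data.frame(contig_id = cid, category = cat_,
                              transcript_id = NA_character_,
                              stringsAsFactors = FALSE))
        }
        s <- a[strict, , drop = FALSE]
        ## greedy disjoint-on-contig selection; truth-preferring tie-break
        s <- s[order(-s$matching_bases, !(s$transcript_id %in% truthIds),
                     s$transcript_id), , drop = FALSE]
        kept <- integer()
        for (i in seq_len(nrow(s))) {
            ok <- TRUE
            for (j in kept) {
                inter <- min(s$query_end[i], s$query_end[j]) -
                    max(s$query_start[i], s$query_start[j])
                shorter <- min(s$query_end[i] - s$query_start[i],
                               s$query_end[j] - s$query_start[j])
                if (inter > 0.5 * shorter) { ok <- FALSE; break }
            }
            if (ok) kept <- c(kept, i)
        }
        hitTx <- unique(s$transcript_id[kept])
        if (length(hitTx) > 1L) {
            genes <- if (is.null(geneMap)) hitTx else unname(geneMap[hitTx])
            cat_ <- if (length(unique(genes)) == 1L) "MA_intra" else "MA_inter"
            return(data.frame(contig_id = cid, category = cat_,
                              transcript_id = NA_character_,
                              stringsAsFactors = FALSE))
        }
        data.frame(contig_id = cid,
                   category = if (hitTx %in% truthIds) "TP" else "FP",
                   transcript_id = hitTx, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Per-transcript reconstruction levels
#'
#' For each truth transcript, the covered fraction is the union of the gated
#' alignment intervals of the contigs assigned to it, divided by its length:
#' \code{complete} at \code{completeFraction} or above, \code{partial} in
#' (0, \code{completeFraction}), \code{missing} at 0.
#'
#' @param assignments data.frame from \code{\link{filterAndAssign}}.
#' @param alignments data.frame from \code{\link{alignToReference}}.
#' @param truthIds truth-set transcript ids.
#' @param config an \code{\link{evalParams}} list.
#' @return data.frame: \code{transcript_id}, \code{covered_fraction},
#'   \code{level}.
#' @export
reconstructionLevels <- function(assignments, alignments, truthIds,
                                 config = evalParams()) {
    lev <- lapply(truthIds, function(t) {
        cids <- assignments$contig_id[assignments$category == "TP" &
                                      !is.na(assignments$transcript_id) &
                                      assignments$transcript_id == t]
        a <- alignments[alignments$query_id %in% cids &
                        alignments$transcript_id == t, , drop = FALSE]
        segLen <- a$target_end - a$target_start
        a <- a[segLen >= config$minSegment &
               a$identity >= config$minIdentity &
               a$largest_indel < config$maxIndel, , drop = FALSE]
        frac <- 0
        if (nrow(a)) {
            ir <- IRanges::reduce(IRanges::IRanges(a$target_start + 1L,
                                                   a$target_end))
            frac <- sum(IRanges::width(ir)) / a$transcript_len[1L]
        }
        level <- if (frac >= config$completeFraction) "complete"
                 else if (frac > 0) "partial" else "missing"
        data.frame(transcript_id = t, covered_fraction = frac, level = level,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, lev)
}

#' Compute evaluation metrics from category counts
#'
#' @param counts named vector or list with \code{complete}, \code{partial},
#'   \code{missing}, \code{FP}, \code{MA_intra}, \code{MA_inter}, \code{LI},
#'   \code{UC} and \code{contigs_tp} (number of contigs representing TP
#'   transcripts).
#' @return an \linkS4class{EvalReport}.
#' @examples
#' computeMetrics(c(complete = 8, partial = 0, missing = 2, FP = 0,
#'                  MA_intra = 0, MA_inter = 1, LI = 1, UC = 0,
#'                  contigs_tp = 10))
#' @export
computeMetrics <- function(counts) {
    counts <- unlist(counts)
    need <- c("complete", "partial", "missing", "FP", "MA_intra", "MA_inter",
              "LI", "UC", "contigs_tp")
    missingNames <- setdiff(need, names(counts))
    if (length(missingNames))
        stop("missing counts: ", paste(missingNames, collapse = ", "))
    TP <- counts[["complete"]] + counts[["partial"]]
    FN <- counts[["missing"]]
    FD <- counts[["FP"]] + counts[["MA_intra"]] + counts[["MA_inter"]] +
        counts[["LI"]] + counts[["UC"]]
    truth <- TP + FN
    recall <- if (truth > 0) 100 * TP / truth else NaN
    FDR <- if (FD + TP > 0) FD / (FD + TP) else {
        warning("FD + TP = 0; FDR reported as 0")
        0
    }
    F1 <- if (TP + 0.5 * (FD + FN) > 0) TP / (TP + 0.5 * (FD + FN)) else 0
    redundancy <- if (TP > 0) counts[["contigs_tp"]] / TP else {
        warning("TP = 0; redundancy undefined")
        NaN
    }
    new("EvalReport",
        counts = c(counts[need], TP = unname(TP), FN = unname(FN),
                   FD = unname(FD)),
        recall = recall, FDR = FDR, F1 = F1, redundancy = redundancy)
}

#' Evaluate an assembly against a reference with a truth subset
#'
#' End-to-end evaluation: align contigs to the reference transcripts, gate
#' and assign, level each truth transcript, and summarize.
#'
#' @param contigs named character vector of assembled transcripts.
#' @param reference named character vector of reference transcripts (must
#'   contain every truth id).
#' @param truthIds transcript ids actually present in the sample.
#' @param geneMap named character vector transcript -> gene.
#' @param config an \code{\link{evalParams}} list.
#' @param alignments optional precomputed \code{\link{alignToReference}}
#'   output.
#' @return list with \code{report} (\linkS4class{EvalReport}),
#'   \code{assignments}, \code{levels}.
#' @export
evaluateAssembly <- function(contigs, reference, truthIds, geneMap = NULL,
                             config = evalParams(), alignments = NULL) {
    contigs <- .as_seqs(contigs)
    reference <- .as_seqs(reference)
    if (!all(truthIds %in% names(reference)))
        stop("truth ids absent from the reference: ",
             paste(setdiff(truthIds, names(reference)), collapse = ", "))
    if (is.null(alignments)) alignments <- alignToReference(contigs, reference)
    assignments <- if (length(contigs) && nrow(alignments))
        filterAndAssign(alignments, truthIds, geneMap, config)
    else data.frame(contig_id = character(), category = character(),
                    transcript_id = character(), stringsAsFactors = FALSE)
    ## contigs with no alignment row at all are unclassified
    noHit <- setdiff(names(contigs), assignments$contig_id)
    if (length(noHit))
        assignments <- rbind(assignments,
                             data.frame(contig_id = noHit, category = "UC",
                                        transcript_id = NA_character_,
                                        stringsAsFactors = FALSE))
    levels <- reconstructionLevels(assignments, alignments, truthIds, config)
    counts <- c(
        complete = sum(levels$level == "complete"),
        partial = sum(levels$level == "partial"),
        missing = sum(levels$level == "missing"),
        FP = length(unique(assignments$transcript_id[
            assignments$category == "FP"])),
        MA_intra = sum(assignments$category == "MA_intra"),
        MA_inter = sum(assignments$category == "MA_inter"),
        LI = sum(assignments$category == "LI"),
        UC = sum(assignments$category == "UC"),
        contigs_tp = sum(assignments$category == "TP" &
                         assignments$transcript_id %in%
                             levels$transcript_id[levels$level != "missing"]))
    list(report = computeMetrics(counts), assignments = assignments,
         levels = levels)
}
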