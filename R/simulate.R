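## Synthetic transcriptome and long-read simulator with ground truth.
## Genes are built from exon pools so isoforms of one gene share exons,
## producing the fork/bubble overlap-graph topologies the assembler must
## resolve; reads get 3'-anchored truncation, poly(A) tails, iid errors,
## random strand in cDNA mode, and an optional chimera fraction.

#' Simulation parameters
#'
#' Defaults emulate a small ONT cDNA experiment: multi-isoform genes with
#' shared exons, log-uniform expression over two orders of magnitude, ~3\%
#' per-base error (2\% substitution, 0.5\% each indel), mostly full-length
#' reads with 3'-anchored truncation otherwise, 10-30 nt poly(A) tails,
#' unknown strand, and a 2\% chimera fraction.
#'
#' @param nGenes number of genes.
#' @param isoformsPerGene integer range (min, max).
#' @param exonLength exon length range in nt.
#' @param exonsPerGene exon-pool size range per gene.
#' @param expressionFold log-uniform expression range (fold).
#' @param subRate,insRate,delRate per-base error rates.
#' @param fullLengthProb probability a read is full length.
#' @param minFrac minimum retained 3'-anchored length fraction for
#'   truncated reads.
#' @param polyALength poly(A) tail length range in nt; \code{c(0, 0)}
#'   disables tails.
#' @param stranded \code{TRUE} emulates dRNA (sense strand only).
#' @param chimeraRate fraction of reads that are fusions of two fragments.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return validated parameter list of class \code{SimConfig}.
#' @export
simParams <- function(nGenes = 5L, isoformsPerGene = c(1L, 3L),
                      exonLength = c(100L, 300L), exonsPerGene = c(4L, 7L),
                      expressionFold = c(1, 200), subRate = 0.02,
                      insRate = 0.005, delRate = 0.005,
                      fullLengthProb = 0.7, minFrac = 0.4,
                      polyALength = c(10L, 30L), stranded = FALSE,
                      chimeraRate = 0.02, seed = 1L) {
    stopifnot(nGenes >= 1, all(c(subRate, insRate, delRate) >= 0),
              all(c(subRate, insRate, delRate) < 1),
              minFrac > 0, minFrac <= 1, chimeraRate >= 0, chimeraRate < 1)
    structure(list(nGenes = as.integer(nGenes),
                   isoformsPerGene = as.integer(isoformsPerGene),
                   exonLength = as.integer(exonLength),
                   exonsPerGene = as.integer(exonsPerGene),
                   expressionFold = expressionFold, subRate = subRate,
                   insRate = insRate, delRate = delRate,
                   fullLengthProb = fullLengthProb, minFrac = minFrac,
                   polyALength = as.integer(polyALength),
                   stranded = stranded, chimeraRate = chimeraRate,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## sample one integer from an inclusive range (safe for degenerate ranges)
.sampleRange <- function(r) if (r[1] >= r[2]) r[1] else r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L

#' Simulate a multi-isoform transcriptome
#'
#' Each gene draws an exon pool; its first isoform uses every exon and the
#' others skip random internal exons, so isoforms of one gene always share
#' the first and last exon (intron-free transcript model: a transcript is
#' the concatenation of its exons).
#'
#' @param config a \code{\link{simParams}} list.
#' @return list with \code{reference} (named character vector of transcript
#'   sequences) and \code{annotation} (data.frame: \code{gene_id},
#'   \code{transcript_id}, \code{exons}, \code{length}).
#' @export
simTranscriptome <- function(config = simParams()) {
    set.seed(config$seed)
    reference <- character()
    ann <- list()
    for (g in seq_len(config$nGenes)) {
        nExon <- .sampleRange(config$exonsPerGene)
        exons <- vapply(seq_len(nExon), function(i)
            .randSeq(.sampleRange(config$exonLength)), character(1))
        nIso <- .sampleRange(config$isoformsPerGene)
        structures <- list(seq_len(nExon))
        tries <- 0L
        while (length(structures) < nIso && tries < 50L) {
            tries <- tries + 1L
            internal <- if (nExon > 2L) 2:(nExon - 1L) else integer()
            if (length(internal) == 0L) break
            nDrop <- .sampleRange(c(1L, length(internal)))
            drop <- sort(sample(internal, nDrop))
            s <- setdiff(seq_len(nExon), drop)
            if (!any(vapply(structures, identical, logical(1), y = s)))
                structures[[length(structures) + 1L]] <- s
        }
        for (i in seq_along(structures)) {
            tid <- sprintf("g%dt%d", g, i)
            reference[tid] <- paste(exons[structures[[i]]], collapse = "")
            ann[[length(ann) + 1L]] <- data.frame(
                gene_id = sprintf("g%d", g), transcript_id = tid,
                exons = paste(structures[[i]], collapse = ","),
                length = nchar(reference[tid]), stringsAsFactors = FALSE)
        }
    }
    list(reference = reference, annotation = do.call(rbind, ann))
}

## apply iid substitution/insertion/deletion errors to one sequence
.mutateSeq <- function(seq, subRate, insRate, delRate) {
    if (subRate + insRate + delRate == 0) return(seq)
    bases <- c("A", "C", "G", "T")
    ch <- strsplit(seq, "")[[1L]]
    n <- length(ch)
    sub <- runif(n) < subRate
    if (any(sub))
        ch[sub] <- vapply(ch[sub], function(b)
            sample(setdiff(bases, b), 1L), character(1))
    del <- runif(n) < delRate
    ins <- runif(n) < insRate
    insBase <- ifelse(ins, sample(bases, n, TRUE), "")
    ch <- ifelse(del, "", ch)
    paste(paste0(ch, insBase), collapse = "")
}

#' Simulate long reads from a reference transcriptome
#'
#' Per-transcript read counts follow the supplied expression weights (or
#' log-uniform weights drawn from \code{expressionFold}). Each read keeps
#' the 3' end of its transcript (full length with probability
#' \code{fullLengthProb}, otherwise a uniform fraction in
#' \code{[minFrac, 1]}), gains a poly(A) tail, then iid errors; in cDNA
#' (unstranded) mode half the reads are reverse-complemented, turning the
#' tail into a 5' poly(T) head. A \code{chimeraRate} fraction of reads are
#' fusions of two independent fragments, flagged in the truth table.
#'
#' @param reference named character vector from \code{\link{simTranscriptome}}.
#' @param config a \code{\link{simParams}} list.
#' @param nReads total number of reads.
#' @param expression optional named weights per transcript.
#' @return list with \code{reads} (data.frame: \code{id}, \code{seq},
#'   \code{qual}) and \code{truth} (data.frame: \code{read_id},
#'   \code{transcript_id}, \code{strand}, \code{is_chimera},
#'   \code{chimera_partner}, \code{junction}).
#' @export
simReads <- function(reference, config = simParams(), nReads = 500L,
                     expression = NULL) {
    set.seed(config$seed + 1L)
    tx <- names(reference)
    if (is.null(expression)) {
        lo <- log(config$expressionFold[1])
        hi <- log(config$expressionFold[2])
        expression <- setNames(exp(runif(length(tx), lo, hi)), tx)
    }
    if (all(expression <= 0)) stop("zero expression everywhere")
    expression <- expression[tx]
    counts <- as.vector(rmultinom(1L, nReads, expression / sum(expression)))
    assign_tx <- rep(tx, counts)

    fragmentOf <- function(t) {
        len <- nchar(reference[[t]])
        frac <- if (runif(1) < config$fullLengthProb) 1
                else runif(1, config$minFrac, 1)
        L <- max(1L, round(frac * len))
        substr(reference[[t]], len - L + 1L, len)
    }
    polyTail <- function() {
        if (config$polyALength[2] <= 0) return("")
        strrep("A", .sampleRange(config$polyALength))
    }

    n <- length(assign_tx)
    ids <- sprintf("sim%05d", seq_len(n))
    seqs <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
        t <- assign_tx[i]
        isChim <- runif(1) < config$chimeraRate
        partner <- NA_character_
        junction <- NA_integer_
        frag <- fragmentOf(t)
        if (isChim) {
            ## template-switch model: the junction lands at a random internal
            ## position of the partner, from which the read runs to its 3'
            ## end, so junction contexts differ between chimeric reads
            partner <- sample(tx, 1L)
            plen <- nchar(reference[[partner]])
            pstart <- .sampleRange(c(1L, max(1L, plen - 100L)))
            junction <- nchar(frag)
            frag <- paste0(frag, substr(reference[[partner]], pstart, plen))
        }
        frag <- paste0(frag, polyTail())
        frag <- .mutateSeq(frag, config$subRate, config$insRate,
                           config$delRate)
        strand <- if (config$stranded || runif(1) < 0.5) "+" else "-"
        if (strand == "-") frag <- revComp(frag)
        seqs[i] <- frag
        truth[[i]] <- data.frame(
            read_id = ids[i], transcript_id = t, strand = strand,
            is_chimera = isChim, chimera_partner = partner,
            junction = junction, stringsAsFactors = FALSE)
    }
    list(reads = data.frame(id = ids, seq = seqs,
                            qual = strrep("I", nchar(seqs)),
                            stringsAsFactors = FALSE),
         truth = do.call(rbind, truth))
}
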