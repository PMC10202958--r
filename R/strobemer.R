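## Stage 2: digital normalization. Read depth is approximated by randstrobe
## multiplicities tracked in a counting Bloom filter; reads are examined in
## descending length order and only reads with a region not yet covered at
## the target depth are added to the minimal longest-reads set (MLRS).

#' Randstrobe parameters
#'
#' A randstrobe of order \eqn{o} links \eqn{o} short "strobes" of length
#' \code{strobeLength}: the first at the anchor position, each next one
#' selected pseudo-randomly (via a hash link function) inside the window
#' \code{[prevEnd + windowMin, prevEnd + windowMax)}. The construct tolerates
#' mismatches and indels between the strobes, which contiguous k-mers do not.
#'
#' @param order number of strobes (default 3).
#' @param strobeLength strobe length in nt (default 10).
#' @param windowMin,windowMax selection window offsets in nt (defaults 15
#'   and 50); \code{strobeLength <= windowMin < windowMax}.
#' @param hashSeed integer seed for the strobe hash.
#' @return validated parameter list of class \code{RandstrobeParams}.
#' @export
strobemerParams <- function(order = 3L, strobeLength = 10L, windowMin = 15L,
                            windowMax = 50L, hashSeed = 17L) {
    stopifnot(order >= 2, windowMin < windowMax, strobeLength <= windowMin)
    structure(list(order = as.integer(order),
                   strobeLength = as.integer(strobeLength),
                   windowMin = as.integer(windowMin),
                   windowMax = as.integer(windowMax),
                   hashSeed = as.integer(hashSeed)),
              class = "RandstrobeParams")
}

#' Digital-normalization parameters
#'
#' @param targetDepth strobemer multiplicity the retained set should reach
#'   everywhere (default 3).
#' @param extremityMargin nt ignored at each read end when judging coverage
#'   (default 50).
#' @return validated parameter list of class \code{NormalizationConfig}.
#' @export
normalizationParams <- function(targetDepth = 3L, extremityMargin = 50L) {
    stopifnot(targetDepth >= 1, extremityMargin >= 0)
    structure(list(targetDepth = as.integer(targetDepth),
                   extremityMargin = as.integer(extremityMargin)),
              class = "NormalizationConfig")
}

#' Compute randstrobes of a sequence
#'
#' One strobemer per anchor position; anchors are limited so that every
#' selection window fits inside the sequence, hence a sequence shorter than
#' \code{strobeLength + (order-1) * windowMax} yields none. Positions whose
#' strobes contain non-ACGT characters are skipped. Deterministic given the
#' hash seed.
#'
#' @param seq a single sequence.
#' @param params a \code{\link{strobemerParams}} list.
#' @return data.frame with \code{start} (0-based anchor), \code{end}
#'   (0-based exclusive end of the last strobe) and \code{hash} (chained,
#'   order-dependent 53-bit strobemer hash).
#' @export
randstrobes <- function(seq, params = strobemerParams()) {
    stopifnot(length(seq) == 1L)
    .randstrobes_cpp(as.character(seq), params$strobeLength,
                     params$windowMin, params$windowMax, params$order,
                     as.double(params$hashSeed))
}

#' Strobemer counter
#'
#' A counting Bloom filter keyed by strobemer hashes, tracking the strobemer
#' multiplicities of the current MLRS.
#'
#' @param expectedStrobemers expected number of distinct strobemers.
#' @param seed hash seed.
#' @return a \linkS4class{CountingBloomFilter}.
#' @export
strobemerCounter <- function(expectedStrobemers = 1e6, seed = 2L)
    countingBloomFilter(expectedStrobemers, counterBits = 8L, seed = seed)

## strobemers of a read in both orientations (unstranded mode maps the
## reverse-complement anchors back into read coordinates)
.readStrobemers <- function(seq, params, stranded) {
    st <- randstrobes(seq, params)
    if (!stranded) {
        rc <- randstrobes(revComp(seq), params)
        if (nrow(rc)) {
            n <- nchar(seq)
            rc2 <- data.frame(start = n - rc$end, end = n - rc$start,
                              hash = rc$hash)
            st <- rbind(st, rc2)
        }
    }
    st
}

#' Is a read represented by the current MLRS?
#'
#' A read is \code{REPRESENTED} when the union of the anchor-to-last-strobe
#' intervals of its strobemers with counter multiplicity at or above the
#' target depth covers the read from \code{extremityMargin} nt after its
#' start to \code{extremityMargin} nt before its end, without a gap;
#' otherwise (including reads too short to yield any strobemer, which are
#' conservatively kept) it is \code{NOT_REPRESENTED}.
#'
#' @param read a single read sequence.
#' @param counter the \code{\link{strobemerCounter}} tracking the MLRS.
#' @param config a \code{\link{normalizationParams}} list.
#' @param params a \code{\link{strobemerParams}} list.
#' @param stranded strand-specific input? When \code{FALSE}, strobemers of
#'   both orientations count.
#' @return \code{"REPRESENTED"} or \code{"NOT_REPRESENTED"}.
#' @export
classifyReadRepresentation <- function(read, counter,
                                       config = normalizationParams(),
                                       params = strobemerParams(),
                                       stranded = TRUE) {
    st <- .readStrobemers(read, params, stranded)
    .classifyFromStrobes(st, nchar(read), counter, config)
}

.classifyFromStrobes <- function(st, len, counter, config) {
    if (nrow(st) == 0L) return("NOT_REPRESENTED")
    cnt <- .cbf_count_hashes(counter@ptr, st$hash)
    covered <- st[cnt >= config$targetDepth, , drop = FALSE]
    lo <- config$extremityMargin
    hi <- len - config$extremityMargin
    if (hi <= lo) return("REPRESENTED")
    if (nrow(covered) == 0L) return("NOT_REPRESENTED")
    ord <- order(covered$start)
    pos <- lo
    for (i in ord) {
        if (covered$start[i] > pos) break
        pos <- max(pos, covered$end[i])
        if (pos >= hi) return("REPRESENTED")
    }
    "NOT_REPRESENTED"
}

#' Digital normalization to the minimal longest-reads set
#'
#' Processes reads longest-first (ties keep input order), one at a time:
#' a read not represented by the MLRS at the target depth is added to the
#' set and its strobemer multiplicities that are still below the target
#' depth are incremented by one; represented reads are dropped and do not
#' increment. Added reads are preserved verbatim.
#'
#' @param reads named character vector (or \code{\link{readFastx}}
#'   data.frame) of error-corrected reads.
#' @param config a \code{\link{normalizationParams}} list.
#' @param params a \code{\link{strobemerParams}} list.
#' @param stranded strand-specific input?
#' @param counter optional pre-sized \code{\link{strobemerCounter}}.
#' @return list with \code{reads} (the retained MLRS, in evaluation order)
#'   and \code{log} (data.frame: \code{read_id}, \code{decision}).
#' @export
digitalNormalize <- function(reads, config = normalizationParams(),
                             params = strobemerParams(), stranded = TRUE,
                             counter = NULL) {
    seqs <- .as_seqs(reads)
    if (length(seqs) == 0L)
        return(list(reads = character(),
                    log = data.frame(read_id = character(),
                                     decision = character())))
    if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
    if (is.null(counter))
        counter <- strobemerCounter(max(1e5, 2 * sum(nchar(seqs))))
    ord <- order(-nchar(seqs))           # stable: ties keep input order
    keep <- logical(length(seqs))
    for (i in ord) {
        st <- .readStrobemers(seqs[[i]], params, stranded)
        decision <- .classifyFromStrobes(st, nchar(seqs[[i]]), counter, config)
        if (decision == "NOT_REPRESENTED") {
            keep[i] <- TRUE
            if (nrow(st))
                .cbf_add_hashes(counter@ptr, st$hash, 1L, config$targetDepth)
        }
    }
    sel <- ord[keep[ord]]
    list(reads = seqs[sel],
         log = data.frame(read_id = names(seqs)[ord],
                          decision = ifelse(keep[ord], "RETAINED", "DROPPED"),
                          stringsAsFactors = FALSE))
}
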