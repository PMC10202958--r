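## Probabilistic membership/counting structures and the k-mer de Bruijn graph
## view used by error correction. The heavy lifting lives in C++; the S4
## classes here hold an external pointer plus the construction parameters.

#' BloomFilter class
#'
#' A plain Bloom filter over byte-string keys: no false negatives, and a
#' false-positive rate on never-inserted keys governed by the analytic
#' expectation \eqn{(1 - e^{-hn/m})^h} for \eqn{n} inserted keys, \eqn{m}
#' bits and \eqn{h} hash functions.
#'
#' @slot ptr external pointer to the C++ bit array.
#' @slot bitCapacity number of bits \eqn{m}.
#' @slot numHashes number of hash functions \eqn{h}.
#' @export
setClass("BloomFilter", representation(ptr = "externalptr",
                                       bitCapacity = "numeric",
                                       numHashes = "integer"))

#' CountingBloomFilter class
#'
#' A counting Bloom filter: a probabilistic multiset whose reported counts are
#' never below the true counts (one-sided error) and saturate at
#' \code{2^counterBits - 1} instead of wrapping.
#'
#' @slot ptr external pointer to the C++ cell array.
#' @slot counterCapacity number of counter cells.
#' @slot counterBits bits per cell; the saturation maximum is
#'   \code{2^counterBits - 1}.
#' @slot numHashes number of hash functions.
#' @export
setClass("CountingBloomFilter", representation(ptr = "externalptr",
                                               counterCapacity = "numeric",
                                               counterBits = "integer",
                                               numHashes = "integer"))

#' KmerGraph class
#'
#' A Bloom-filter de Bruijn graph: k-mer membership in a Bloom filter and
#' approximate k-mer multiplicities in a counting Bloom filter. In canonical
#' mode each k-mer is collapsed with its reverse complement (non-strand-
#' specific cDNA input); in non-canonical mode k-mers are stored as read
#' (stranded dRNA input).
#'
#' @slot ptr external pointer to the C++ structure.
#' @slot k k-mer length.
#' @slot canonical logical; strand-collapsed k-mers?
#' @export
setClass("KmerGraph", representation(ptr = "externalptr", k = "integer",
                                     canonical = "logical"))

#' Create a Bloom filter
#'
#' @param expectedKeys expected number of distinct keys; with \code{fpr} this
#'   determines the bit capacity and hash count analytically.
#' @param fpr target false-positive rate at the expected load (default 0.01).
#' @param seed integer seed for the hash functions.
#' @return a \linkS4class{BloomFilter}.
#' @examples
#' bf <- bloomFilter(1000)
#' bloomInsert(bf, "ACGTA")
#' bloomContains(bf, c("ACGTA", "TTTTT"))
#' @export
bloomFilter <- function(expectedKeys, fpr = 0.01, seed = 1L) {
    stopifnot(expectedKeys >= 1, fpr > 0, fpr < 1)
    ln2 <- log(2)
    m <- ceiling(-expectedKeys * log(fpr) / ln2^2)
    h <- max(1L, min(10L, as.integer(round(m / expectedKeys * ln2))))
    new("BloomFilter", ptr = .bf_new(m, h, as.double(seed)),
        bitCapacity = m, numHashes = h)
}

#' Insert keys into a Bloom filter
#' @param filter a \linkS4class{BloomFilter}.
#' @param keys character vector of non-empty keys.
#' @return the filter, invisibly (updated in place).
#' @export
bloomInsert <- function(filter, keys) {
    stopifnot(is(filter, "BloomFilter"), all(nzchar(keys)))
    .bf_insert(filter@ptr, as.character(keys))
    invisible(filter)
}

#' Query a Bloom filter
#' @inheritParams bloomInsert
#' @return logical vector; inserted keys always return \code{TRUE}.
#' @export
bloomContains <- function(filter, keys) {
    stopifnot(is(filter, "BloomFilter"))
    .bf_contains(filter@ptr, as.character(keys))
}

#' @describeIn bloomFilter number of keys inserted so far.
#' @param filter a \linkS4class{BloomFilter}.
#' @export
bloomInsertedCount <- function(filter) .bf_info(filter@ptr)$inserted_count

setMethod("show", "BloomFilter", function(object) {
    info <- .bf_info(object@ptr)
    cat(sprintf("BloomFilter: %.0f bits, %d hashes, %.0f keys inserted\n",
                info$bit_capacity, info$num_hashes, info$inserted_count))
})

#' Create a counting Bloom filter
#'
#' @param expectedKeys expected number of distinct keys.
#' @param counterBits bits per saturating counter cell (default 8, so counts
#'   saturate at 255 and never wrap).
#' @param fpr target false-positive rate used to size the structure.
#' @param seed hash seed.
#' @return a \linkS4class{CountingBloomFilter}.
#' @export
countingBloomFilter <- function(expectedKeys, counterBits = 8L, fpr = 0.01,
                                seed = 1L) {
    stopifnot(expectedKeys >= 1, counterBits >= 1)
    ln2 <- log(2)
    m <- ceiling(-expectedKeys * log(fpr) / ln2^2 / 4)
    h <- max(1L, min(10L, as.integer(round(m / expectedKeys * ln2))))
    new("CountingBloomFilter", ptr = .cbf_new(m, as.integer(counterBits), h,
                                              as.double(seed)),
        counterCapacity = m, counterBits = as.integer(counterBits),
        numHashes = h)
}

#' Increment counts in a counting Bloom filter
#'
#' Increments each key's counters by \code{increments} (saturating) and
#' returns the new reported counts. Reported counts are always greater than
#' or equal to the true number of increments.
#'
#' @param counter a \linkS4class{CountingBloomFilter}.
#' @param keys character vector of keys.
#' @param increments non-negative integer added to each key's count.
#' @return integer vector of reported counts after the update.
#' @export
cbfIncrement <- function(counter, keys, increments = 1L) {
    stopifnot(is(counter, "CountingBloomFilter"), increments >= 0)
    .cbf_add(counter@ptr, as.character(keys), as.integer(increments))
}

#' @rdname cbfIncrement
#' @export
cbfCount <- function(counter, keys) {
    stopifnot(is(counter, "CountingBloomFilter"))
    .cbf_count(counter@ptr, as.character(keys))
}

setMethod("show", "CountingBloomFilter", function(object) {
    cat(sprintf("CountingBloomFilter: %.0f cells x %d bits, %d hashes\n",
                object@counterCapacity, object@counterBits, object@numHashes))
})

#' Build a k-mer multiplicity graph from reads
#'
#' Ingests every valid k-mer (k-mers containing non-ACGT characters are
#' skipped) of the long reads, and optionally of accompanying short reads,
#' into a Bloom-filter de Bruijn graph with approximate multiplicities.
#' Short reads, when supplied, are ingested into the same graph so that
#' their k-mers aid error correction of the long reads.
#'
#' @param longReads character vector of read sequences (or a data.frame with
#'   a \code{seq} column as returned by \code{\link{readFastx}}).
#' @param shortReads optional character vector of short-read sequences.
#' @param k odd k-mer length \eqn{\ge} 11 (default 25).
#' @param canonical collapse k-mers with their reverse complements (use
#'   \code{TRUE} for non-strand-specific cDNA input).
#' @param expectedKmers expected number of distinct k-mers, used to size the
#'   Bloom filters for a ~1\% false-positive rate; defaults to the total
#'   input base count.
#' @param seed hash seed.
#' @return a \linkS4class{KmerGraph}.
#' @examples
#' g <- buildKmerGraph("ACGTACGT", k = 5, canonical = FALSE)
#' kmerCounts(g, "ACGTACGT")
#' @export
buildKmerGraph <- function(longReads, shortReads = NULL, k = 25L,
                           canonical = TRUE, expectedKmers = NULL, seed = 1L) {
    longReads <- .as_seqs(longReads)
    if (length(longReads) == 0L) stop("empty input read set")
    k <- as.integer(k)
    stopifnot(k >= 2, k <= 32)
    if (k %% 2L == 0L && canonical)
        stop("k must be odd so that canonical k-mers are well-defined")
    shortReads <- if (is.null(shortReads)) character() else .as_seqs(shortReads)
    if (is.null(expectedKmers))
        expectedKmers <- sum(nchar(longReads)) + sum(nchar(shortReads))
    g <- .kg_new(k, canonical, as.double(expectedKmers), 0.01, as.double(seed))
    tooShort <- sum(nchar(longReads) < k)
    if (tooShort > 0)
        warning(sprintf("%d read(s) shorter than k = %d contribute no k-mers",
                        tooShort, k))
    .kg_ingest(g, longReads)
    if (length(shortReads)) .kg_ingest(g, shortReads)
    new("KmerGraph", ptr = g, k = k, canonical = canonical)
}

#' Multiplicity of every k-mer along a read
#'
#' @param graph a \linkS4class{KmerGraph}.
#' @param read a single read sequence.
#' @return integer vector of length \code{nchar(read) - k + 1}: the reported
#'   multiplicity of each k-mer, or -1 where the k-mer contains a non-ACGT
#'   base. Zero-length for reads shorter than k.
#' @export
kmerCounts <- function(graph, read) {
    stopifnot(is(graph, "KmerGraph"), length(read) == 1L)
    .kg_read_counts(graph@ptr, as.character(read))
}

#' @rdname kmerCounts
#' @param kmers character vector of k-length sequences.
#' @export
kmerMultiplicity <- function(graph, kmers) {
    stopifnot(is(graph, "KmerGraph"))
    .kg_count(graph@ptr, as.character(kmers))
}

#' @rdname kmerCounts
#' @export
hasKmer <- function(graph, kmers) {
    stopifnot(is(graph, "KmerGraph"))
    .kg_contains(graph@ptr, as.character(kmers))
}

#' Neighbors of a k-mer in the de Bruijn graph
#'
#' @param graph a \linkS4class{KmerGraph}.
#' @param kmer a single k-length sequence.
#' @param direction \code{"right"} for single-base 3' extensions,
#'   \code{"left"} for 5' extensions.
#' @return data.frame with columns \code{kmer} and \code{count}: the subset
#'   of the four possible extensions present in the graph.
#' @export
kmerNeighbors <- function(graph, kmer, direction = c("right", "left")) {
    stopifnot(is(graph, "KmerGraph"), length(kmer) == 1L)
    direction <- match.arg(direction)
    nb <- .kg_neighbors(graph@ptr, as.character(kmer), direction == "right")
    data.frame(kmer = as.character(nb$kmer), count = as.integer(nb$count),
               stringsAsFactors = FALSE)
}

setMethod("show", "KmerGraph", function(object) {
    info <- .kg_info(object@ptr)
    cat(sprintf(
        "KmerGraph: k = %d (%s), %.0f k-mer occurrences ingested, %.0f bits\n",
        info$k, if (info$canonical) "canonical" else "stranded",
        info$kmers_ingested, info$bit_capacity))
})

## Accept either a bare character vector or a data.frame with a seq column.
.as_seqs <- function(x) {
    if (is.data.frame(x)) {
        s <- as.character(x$seq)
        if (!is.null(x$id)) names(s) <- as.character(x$id)
        s
    } else {
        s <- as.character(x)
        names(s) <- names(x)
        s
    }
}
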