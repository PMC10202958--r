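## Independent oracles and small fixture builders shared across tests.

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## reverse complement without touching the package's C++ routine
rcOracle <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                  character(1), USE.NAMES = FALSE))
}

## exact k-mer counting with a hash map (named table)
kmerCountOracle <- function(reads, k, canonical = TRUE) {
    counts <- new.env(hash = TRUE)
    for (r in reads) {
        n <- nchar(r)
        if (n < k) next
        for (i in seq_len(n - k + 1)) {
            km <- substr(r, i, i + k - 1)
            if (grepl("[^ACGT]", km)) next
            if (canonical) km <- min(km, rcOracle(km))
            counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
        }
    }
    out <- unlist(as.list(counts))
    if (is.null(out)) integer() else out
}

## brute-force exact suffix-prefix dovetail finder (plus-strand only)
suffixPrefixOracle <- function(seqs, minOverlap) {
    ids <- names(seqs)
    out <- list()
    for (a in ids) for (b in ids) {
        if (a == b) next
        la <- nchar(seqs[[a]]); lb <- nchar(seqs[[b]])
        for (ov in min(la, lb):minOverlap) {
            if (substr(seqs[[a]], la - ov + 1, la) == substr(seqs[[b]], 1, ov)) {
                out[[length(out) + 1]] <- data.frame(
                    from = a, to = b, overlap = ov, stringsAsFactors = FALSE)
                break
            }
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(from = character(), to = character(), overlap = integer())
}

## naive all-pairs transitive reduction oracle on an OverlapGraph
naiveReductionOracle <- function(graph, fuzz = 10L) {
    e <- graphEdges(graph)
    v <- graphVertices(graph)
    lenOf <- setNames(v$len, v$vid)
    ext <- unname(lenOf[e$to]) - e$to_end
    key <- paste(e$from, e$to)
    extOf <- setNames(ext, key)
    drop <- logical(nrow(e))
    for (i in seq_len(nrow(e))) {      # is e[i] = u->w implied by u->v->w?
        u <- e$from[i]; w <- e$to[i]
        for (j in which(e$from == u)) {
            v2 <- e$to[j]
            if (v2 == w) next
            k2 <- paste(v2, w)
            if (k2 %in% key &&
                abs(ext[j] + extOf[[k2]] - ext[i]) <= fuzz) {
                drop[i] <- TRUE
                break
            }
        }
    }
    e[!drop, , drop = FALSE]
}

## exact binomial CDF by direct enumeration (no pbinom)
binomCdfOracle <- function(s, n, p) {
    if (n == 0) return(1)
    k <- 0:min(s, n)
    sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

## construct an annotated unitig OverlapGraph directly from seed components:
## seqs named by unitig, edges as data.frame(from, to) of unitig ids with
## suffix-prefix overlap length ov, counts named by unitig
makeUnitigGraphFixture <- function(seqs, edges, counts, support = NULL) {
    v <- data.frame(vid = paste0(names(seqs), "+"), id = names(seqs),
                    orient = "+", len = nchar(seqs), pref = NA_character_,
                    count = unname(counts[names(seqs)]),
                    stringsAsFactors = FALSE)
    if (nrow(edges)) {
        lenOf <- setNames(nchar(seqs), names(seqs))
        e <- data.frame(from = paste0(edges$from, "+"),
                        to = paste0(edges$to, "+"),
                        from_start = unname(lenOf[edges$from]) - edges$ov,
                        from_end = unname(lenOf[edges$from]),
                        to_start = 0L, to_end = edges$ov, olen = edges$ov,
                        stringsAsFactors = FALSE)
        e$support <- if (is.null(support)) rep(0L, nrow(e)) else support
    } else {
        e <- data.frame(from = character(), to = character(),
                        from_start = integer(), from_end = integer(),
                        to_start = integer(), to_end = integer(),
                        olen = integer(), support = integer(),
                        stringsAsFactors = FALSE)
    }
    new("OverlapGraph", vertices = v, edges = e, stranded = TRUE)
}

## measured per-base error rate of reads against their true source sequences
errorRateOracle <- function(reads, truthTx, reference) {
    tot <- c(err = 0, len = 0)
    for (t in unique(truthTx)) {
        ids <- names(reads)[truthTx == t]
        if (length(ids) == 0) next
        a <- alignReadsTo(reads[ids], reference[[t]], minSharedKmers = 3L)
        tot["err"] <- tot["err"] + sum(a$block_len - a$matching_bases)
        tot["len"] <- tot["len"] + sum(a$block_len)
    }
    unname(tot["err"] / tot["len"])
}
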