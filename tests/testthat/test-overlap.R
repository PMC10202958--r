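test_that("an exact suffix-prefix overlap is reported with exact coordinates", {
    set.seed(41)
    s <- rseq(1000)
    seqs <- c(A = substr(s, 1, 700), B = substr(s, 401, 1000))
    ov <- findReadOverlaps(seqs, minOverlap = 150, stranded = TRUE)
    expect_identical(nrow(ov), 1L)
    expect_identical(ov$query_id, "A")
    expect_identical(ov$target_id, "B")
    expect_identical(c(ov$query_start, ov$query_end), c(400L, 700L))
    expect_identical(c(ov$target_start, ov$target_end), c(0L, 300L))
    expect_identical(ov$strand, "+")
    expect_error(findReadOverlaps(c(A = "ACGT", A = "ACGT")), "duplicate")
})

test_that("containment and reverse-complement overlaps classify correctly", {
    set.seed(42)
    big <- rseq(900)
    seqs <- c(big = big, small = substr(big, 201, 700))
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = TRUE))
    expect_identical(nrow(ov), 1L)
    type <- ifelse(ov$query_id == "small", "CONTAINED", "CONTAINS")
    expect_identical(ov$type, unname(type))

    ## reverse-complemented suffix: minus-strand record, suppressed when
    ## stranded
    rcpair <- c(A = substr(big, 1, 600),
                B = rcOracle(substr(big, 301, 900)))
    ovU <- findReadOverlaps(rcpair, minOverlap = 150, stranded = FALSE)
    expect_identical(ovU$strand, "-")
    ovS <- findReadOverlaps(rcpair, minOverlap = 150, stranded = TRUE)
    expect_identical(nrow(ovS), 0L)
})

test_that("overhang geometry drives the overlap classification", {
    rec <- data.frame(query_id = "q", query_len = 1000L, query_start = 10L,
                      query_end = 990L, strand = "+", target_id = "t",
                      target_len = 2000L, target_start = 500L,
                      target_end = 1480L, matching_bases = 950L,
                      block_len = 980L, identity = 0.97,
                      stringsAsFactors = FALSE)
    expect_identical(classifyOverlaps(rec)$type, "CONTAINED")

    dovetail <- rec
    dovetail$query_start <- 600L; dovetail$query_end <- 1000L
    dovetail$target_start <- 0L; dovetail$target_end <- 400L
    expect_identical(classifyOverlaps(dovetail)$type, "DOVETAIL_QT")

    internal <- rec
    internal$query_start <- 400L; internal$query_end <- 600L
    internal$target_start <- 900L; internal$target_end <- 1100L
    expect_identical(classifyOverlaps(internal)$type, "INTERNAL")
})

test_that("PAF writing and parsing round-trip, with identity from columns 10/11", {
    set.seed(43)
    s <- rseq(800)
    seqs <- c(x = substr(s, 1, 500), y = substr(s, 201, 800))
    ov <- findReadOverlaps(seqs, minOverlap = 150, stranded = TRUE)
    path <- tempfile(fileext = ".paf")
    writePAF(ov, path)
    back <- readPAF(path)
    for (col in c("query_id", "query_len", "query_start", "query_end",
                  "strand", "target_id", "target_len", "target_start",
                  "target_end", "matching_bases", "block_len"))
        expect_identical(back[[col]], ov[[col]])

    line <- "q\t400\t0\t300\t+\tt\t500\t100\t400\t285\t300\t60"
    writeLines(line, path)
    rec <- readPAF(path)
    expect_equal(rec$identity, 285 / 300)

    writeLines(character(), path)
    expect_identical(nrow(readPAF(path)), 0L)

    writeLines("q\t400\t0\t300", path)
    expect_error(readPAF(path), "line 1")
})

test_that("reported dovetails cover the exact-overlap oracle within 2 nt", {
    set.seed(44)
    for (rep in 1:3) {
        genome <- rseq(3000)
        starts <- sort(sample(0:2400, 8))
        seqs <- setNames(vapply(starts, function(st)
            substr(genome, st + 1, min(st + 800, 3000)), character(1)),
            paste0("r", seq_along(starts)))
        seqs <- seqs[!duplicated(seqs)]
        oracle <- suffixPrefixOracle(seqs, 150)
        found <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                                   stranded = TRUE))
        for (i in seq_len(nrow(oracle))) {
            a <- oracle$from[i]; b <- oracle$to[i]
            hit <- found[(found$query_id == a & found$target_id == b) |
                         (found$query_id == b & found$target_id == a), ,
                         drop = FALSE]
            expect_gte(nrow(hit), 1L)
            spans <- pmin(hit$query_end - hit$query_start,
                          hit$target_end - hit$target_start)
            expect_lte(abs(max(spans) - oracle$overlap[i]), 2L)
        }
    }
})

test_that("overlaps of reverse-complemented input are the strand-flipped images", {
    set.seed(45)
    s <- rseq(1100)
    seqs <- c(A = substr(s, 1, 700), B = substr(s, 401, 1100))
    fwd <- findReadOverlaps(seqs, minOverlap = 150, stranded = FALSE)
    flip <- c(A = seqs[["A"]], B = rcOracle(seqs[["B"]]))
    rev <- findReadOverlaps(flip, minOverlap = 150, stranded = FALSE)
    expect_identical(nrow(rev), nrow(fwd))
    expect_identical(rev$strand, ifelse(fwd$strand == "+", "-", "+"))
    expect_identical(rev$query_start, fwd$query_start)
    expect_identical(rev$target_len - rev$target_end, fwd$target_start)
})
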