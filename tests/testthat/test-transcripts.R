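test_that("normalized read counts divide aligned bases by unitig length", {
    a <- data.frame(query_id = paste0("r", 1:10),
                    target_start = rep(0L, 10), target_end = rep(500L, 10))
    expect_equal(normalizedReadCount(a, 1000L), 5.0)
    expect_equal(normalizedReadCount(a[0, ], 1000L), 0.0)
    expect_error(normalizedReadCount(a, 0L), "zero-length")

    ## a straddling read splits its contribution by aligned bases
    strA <- data.frame(query_id = "r", target_start = 0L, target_end = 800L)
    strB <- data.frame(query_id = "r", target_start = 0L, target_end = 200L)
    expect_equal(normalizedReadCount(strA, 1000L), 0.8)
    expect_equal(normalizedReadCount(strB, 1000L), 0.2)
})

test_that("binomial edge filter matches exact CDF enumeration", {
    ## spec-level examples
    mk <- function(cu, cv, s) {
        g <- makeUnitigGraphFixture(
            setNames(c(rseq(300), rseq(300)), c("u", "v")),
            data.frame(from = "u", to = "v", ov = 100L),
            c(u = cu, v = cv), support = s)
    }
    set.seed(81)
    expect_identical(nrow(graphEdges(binomialEdgeFilter(mk(20, 20, 1L)))), 0L)
    expect_identical(nrow(graphEdges(binomialEdgeFilter(mk(4, 400, 2L)))), 1L)
    expect_identical(nrow(graphEdges(binomialEdgeFilter(mk(2, 2, 0L)))), 1L)

    ## full enumeration n <= 20, s <= n, p in {0.25, 0.5}
    for (p in c(0.25, 0.5)) {
        for (n in 0:20) {
            for (s in 0:n) {
                g <- mk(n, n, s)
                kept <- nrow(graphEdges(
                    binomialEdgeFilter(g, alpha = 0.05, spanningProb = p))) == 1L
                expectKept <- n < 3 || binomCdfOracle(s, n, p) >= 0.05
                expect_identical(kept, expectKept)
            }
        }
    }
})

test_that("unitigs are reoriented by poly(A) read alignments", {
    set.seed(82)
    seqs <- setNames(c(rseq(400), rseq(400)), c("u1", "u2"))
    v <- data.frame(vid = c("u1+", "u1-", "u2+", "u2-"),
                    id = rep(c("u1", "u2"), each = 2),
                    orient = rep(c("+", "-"), 2),
                    len = rep(400L, 4), pref = NA_character_,
                    count = rep(5, 4), stringsAsFactors = FALSE)
    ## antisense join: u1+ -> u2- (and mirror)
    e <- data.frame(from = c("u1+", "u2+"), to = c("u2-", "u1-"),
                    from_start = 300L, from_end = 400L,
                    to_start = 0L, to_end = 100L, olen = 100L,
                    support = 3L, stringsAsFactors = FALSE)
    g <- new("OverlapGraph", vertices = v, edges = e, stranded = FALSE)
    signals <- data.frame(read_id = paste0("r", 1:10),
                          kind = "TAIL_A", tail_length = 15L,
                          stringsAsFactors = FALSE)
    alignments <- list(
        u1 = data.frame(query_id = paste0("r", 1:5), strand = "+",
                        query_len = 400L, query_start = 0L,
                        query_end = 400L, target_start = 0L,
                        target_end = 400L, stringsAsFactors = FALSE),
        u2 = data.frame(query_id = paste0("r", 6:10), strand = "+",
                        query_len = 400L, query_start = 0L,
                        query_end = 400L, target_start = 0L,
                        target_end = 400L, stringsAsFactors = FALSE))
    out <- reorientByPolyA(g, signals, alignments)
    ## both unitigs fixed forward; the antisense edge is inconsistent -> gone
    expect_setequal(graphVertices(out)$vid, c("u1+", "u2+"))
    expect_identical(nrow(graphEdges(out)), 0L)

    ## majority rules under conflicting evidence (3 forward vs 2 reverse)
    alignments2 <- list(
        u1 = data.frame(query_id = paste0("r", 1:5),
                        strand = c("+", "+", "+", "-", "-"),
                        query_len = 400L, query_start = 0L,
                        query_end = 400L, target_start = 0L,
                        target_end = 400L, stringsAsFactors = FALSE),
        u2 = alignments$u2)
    out2 <- reorientByPolyA(g, signals, alignments2)
    expect_true("u1+" %in% graphVertices(out2)$vid)
    expect_identical(attr(out2, "orientConflicts"), "u1")
})

test_that("greedy extraction follows counts and decrements by path minima", {
    set.seed(83)
    ## linear chain with counts 9, 8, 7: one transcript, residuals 2, 1, 0
    core <- rseq(900)
    seqs <- c(a = substr(core, 1, 400), b = substr(core, 301, 700),
              c = substr(core, 601, 900))
    edges <- data.frame(from = c("a", "b"), to = c("b", "c"),
                        ov = c(100L, 100L))
    g <- makeUnitigGraphFixture(seqs, edges, c(a = 9, b = 8, c = 7),
                                support = c(5L, 5L))
    res <- greedyAssembleTranscripts(g, seqs)
    expect_identical(length(res$transcripts), 1L)
    expect_identical(unname(res$transcripts), core)
    expect_equal(res$info$min_count, 7)

    ## two isoforms sharing the middle unitig M
    M <- rseq(400)
    seqs2 <- c(A1 = paste0(rseq(200), substr(M, 1, 100)),
               A2 = paste0(rseq(200), substr(M, 1, 100)),
               M = M,
               B1 = paste0(substr(M, 301, 400), rseq(200)),
               B2 = paste0(substr(M, 301, 400), rseq(200)))
    edges2 <- data.frame(from = c("A1", "A2", "M", "M"),
                         to = c("M", "M", "B1", "B2"),
                         ov = rep(100L, 4))
    g2 <- makeUnitigGraphFixture(seqs2, edges2,
                                 c(A1 = 6, A2 = 4, M = 10, B1 = 6, B2 = 4),
                                 support = rep(3L, 4))
    res2 <- greedyAssembleTranscripts(g2, seqs2)
    expect_identical(length(res2$transcripts), 2L)
    expect_equal(res2$info$min_count, c(6, 4))
    expect_identical(res2$info$path,
                     c("A1+,M+,B1+", "A2+,M+,B2+"))
    expect_identical(unname(res2$transcripts[1]),
                     paste0(seqs2[["A1"]], substr(M, 101, 400),
                            rseq(0), substring(seqs2[["B1"]], 101)))

    ## a 3-cycle terminates with exactly one transcript
    s3 <- rseq(600)
    seqs3 <- c(x = paste0(substr(s3, 401, 600), substr(s3, 1, 200)),
               y = substr(s3, 101, 400),
               z = substr(s3, 301, 600))
    edges3 <- data.frame(from = c("x", "y", "z"), to = c("y", "z", "x"),
                         ov = rep(100L, 3))
    g3 <- makeUnitigGraphFixture(seqs3, edges3, c(x = 5, y = 4, z = 3),
                                 support = rep(2L, 3))
    res3 <- greedyAssembleTranscripts(g3, seqs3)
    expect_identical(length(res3$transcripts), 1L)
})

test_that("extraction conserves counts and always terminates", {
    set.seed(84)
    for (rep in 1:5) {
        n <- sample(4:8, 1)
        seqs <- setNames(vapply(seq_len(n), function(i) rseq(300),
                                character(1)), paste0("u", seq_len(n)))
        pairs <- expand.grid(from = names(seqs), to = names(seqs),
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$from != pairs$to, ]
        pairs <- pairs[sample(nrow(pairs), min(nrow(pairs), n + 2)), ]
        edges <- data.frame(from = pairs$from, to = pairs$to,
                            ov = rep(50L, nrow(pairs)))
        counts <- setNames(sample(0:10, n, TRUE), names(seqs))
        g <- makeUnitigGraphFixture(seqs, edges, counts,
                                    support = rep(1L, nrow(edges)))
        res <- greedyAssembleTranscripts(g, seqs)   # must terminate
        expect_lte(sum(res$info$min_count), sum(counts))
    }
})
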