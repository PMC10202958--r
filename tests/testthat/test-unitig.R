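test_that("poly(A) tails and poly(T) heads are detected with purity gates", {
    set.seed(61)
    base <- rseq(200)
    pa <- detectPolyA(paste0(base, "GTC", strrep("A", 15)))
    expect_identical(pa$kind, "TAIL_A")
    expect_identical(pa$tail_length, 15L)

    pt <- detectPolyA(paste0(strrep("T", 12), base))
    expect_identical(pt$kind, "HEAD_T")

    ## both present: TAIL_A takes precedence
    both <- detectPolyA(paste0(strrep("T", 12), base, strrep("A", 12)))
    expect_identical(both$kind, "TAIL_A")

    ## seeded sequence with no homopolymer of 6+: no signal
    noRun <- paste(rep("ACGT", 60), collapse = "")
    expect_identical(detectPolyA(noRun)$kind, "NONE")
})

test_that("overlap graph vertices and edges follow the strand mode", {
    set.seed(62)
    s <- rseq(1200)
    seqs <- c(a = substr(s, 1, 600), b = substr(s, 301, 900),
              c = substr(s, 601, 1200))
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = TRUE))
    g <- buildOverlapGraph(ov, seqs, stranded = TRUE)
    expect_identical(nrow(graphVertices(g)), 3L)
    expect_identical(nrow(graphEdges(g)), 2L)
    expect_setequal(graphEdges(g)$from, c("a+", "b+"))

    ovU <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                             stranded = FALSE))
    gU <- buildOverlapGraph(ovU, seqs, stranded = FALSE)
    expect_identical(nrow(graphVertices(gU)), 6L)
    expect_identical(nrow(graphEdges(gU)), 4L)   # mirrored edges

    ## minus-strand overlap contributes no edge in stranded mode
    rcpair <- c(x = substr(s, 1, 600), y = rcOracle(substr(s, 301, 900)))
    ovS <- classifyOverlaps(findReadOverlaps(rcpair, minOverlap = 150,
                                             stranded = FALSE))
    gS <- buildOverlapGraph(ovS, rcpair, stranded = TRUE)
    expect_identical(nrow(graphEdges(gS)), 0L)
})

test_that("poly(A) pruning removes tail extensions and antisense joins", {
    set.seed(63)
    core <- rseq(400)
    ## A ends in the shared core + tail; B continues downstream of A
    A <- paste0(rseq(200), core, strrep("A", 15))
    B <- paste0(core, strrep("A", 15), rseq(200))
    seqs <- c(A = A, B = B)
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = FALSE))
    g <- buildOverlapGraph(ov, seqs, stranded = FALSE)
    sig <- detectPolyASignals(seqs)
    expect_identical(sig$kind[sig$read_id == "A"], "TAIL_A")
    pruned <- pruneByPolyA(g, sig)
    ## any 3'-extending edge out of A's preferred orientation is gone
    expect_false(any(graphEdges(pruned)$from == "A+"))

    ## head-to-head: two TAIL_A reads overlapping antisense at their 5' ends
    ua <- rseq(250); ub <- rseq(250)
    shared <- rseq(300)
    A2 <- paste0(shared, ua, strrep("A", 15))
    B2 <- paste0(rcOracle(shared), ub, strrep("A", 15))
    seqs2 <- c(A2 = A2, B2 = B2)
    ov2 <- classifyOverlaps(findReadOverlaps(seqs2, minOverlap = 150,
                                             stranded = FALSE))
    g2 <- buildOverlapGraph(ov2, seqs2, stranded = FALSE)
    expect_gt(nrow(graphEdges(g2)), 0L)
    pruned2 <- pruneByPolyA(g2, detectPolyASignals(seqs2))
    expect_identical(nrow(graphEdges(pruned2)), 0L)

    ## no signals: graph unchanged
    g3 <- pruneByPolyA(g2, detectPolyASignals(c(A2 = rseq(100))))
    expect_identical(nrow(graphEdges(g3)), nrow(graphEdges(g2)))
})

test_that("transitive reduction removes exactly the implied edges", {
    set.seed(64)
    s <- rseq(1500)
    ## u, v, w staggered so u->v, v->w and the transitive u->w all exist
    seqs <- c(u = substr(s, 1, 800), v = substr(s, 301, 1100),
              w = substr(s, 601, 1400))
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = TRUE))
    g <- buildOverlapGraph(ov, seqs, stranded = TRUE)
    expect_identical(nrow(graphEdges(g)), 3L)
    red <- transitiveReduce(g)
    expect_identical(nrow(graphEdges(red)), 2L)
    expect_false(any(graphEdges(red)$from == "u+" &
                     graphEdges(red)$to == "w+"))

    ## a plain path has nothing to remove
    seqs2 <- c(u = substr(s, 1, 700), v = substr(s, 401, 1100),
               w = substr(s, 801, 1500))
    ov2 <- classifyOverlaps(findReadOverlaps(seqs2, minOverlap = 150,
                                             stranded = TRUE))
    g2 <- buildOverlapGraph(ov2, seqs2, stranded = TRUE)
    expect_identical(nrow(graphEdges(transitiveReduce(g2))),
                     nrow(graphEdges(g2)))
})

test_that("reduction matches the brute-force oracle and preserves reachability", {
    set.seed(65)
    for (rep in 1:10) {
        genome <- rseq(2500)
        nReads <- sample(8:15, 1)
        starts <- sort(sample(0:1900, nReads))
        seqs <- setNames(vapply(starts, function(st)
            substr(genome, st + 1, min(st + sample(500:700, 1), 2500)),
            character(1)), paste0("r", seq_len(nReads)))
        seqs <- seqs[!duplicated(seqs)]
        ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                                stranded = TRUE))
        contained <- unique(c(ov$query_id[ov$type == "CONTAINED"],
                              ov$target_id[ov$type == "CONTAINS"]))
        seqs <- seqs[setdiff(names(seqs), contained)]
        g <- buildOverlapGraph(ov, seqs, stranded = TRUE)
        red <- transitiveReduce(g)
        oracle <- naiveReductionOracle(g)
        expect_setequal(paste(graphEdges(red)$from, graphEdges(red)$to),
                        paste(oracle$from, oracle$to))

        ## reachability is preserved
        reach <- function(edges, from) {
            seen <- from
            repeat {
                nxt <- unique(edges$to[edges$from %in% seen])
                if (all(nxt %in% seen)) return(sort(seen))
                seen <- union(seen, nxt)
            }
        }
        for (v in graphVertices(g)$vid)
            expect_identical(reach(graphEdges(red), v),
                             reach(graphEdges(g), v))
    }
})

test_that("unambiguous paths splice into exact unitigs; forks break paths", {
    set.seed(66)
    tx <- rseq(1500)
    seqs <- c(r1 = substr(tx, 1, 600), r2 = substr(tx, 301, 900),
              r3 = substr(tx, 601, 1200), r4 = substr(tx, 901, 1500))
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = TRUE))
    g <- transitiveReduce(buildOverlapGraph(ov, seqs, stranded = TRUE))
    un <- assembleUnitigs(g, seqs)
    expect_identical(length(un$unitigs), 1L)
    expect_identical(unname(un$unitigs), tx)   # byte-identical reconstruction

    ## Y-fork: shared stem with two alternative continuations -> 3 unitigs
    stem <- rseq(400); b1 <- rseq(400); b2 <- rseq(400)
    fseqs <- c(s = stem, x = paste0(substr(stem, 201, 400), b1),
               y = paste0(substr(stem, 201, 400), b2))
    fov <- classifyOverlaps(findReadOverlaps(fseqs, minOverlap = 150,
                                             stranded = TRUE))
    fg <- transitiveReduce(buildOverlapGraph(fov, fseqs, stranded = TRUE))
    fun <- assembleUnitigs(fg, fseqs)
    expect_identical(length(fun$unitigs), 3L)
    expect_setequal(vapply(fun$paths, paste, character(1), collapse = ","),
                    c("s+", "x+", "y+"))

    ## singleton vertex -> the read itself
    lone <- c(z = rseq(500))
    lg <- buildOverlapGraph(classifyOverlaps(
        findReadOverlaps(c(lone, zz = rseq(500)), minOverlap = 150,
                         stranded = TRUE)), lone, stranded = TRUE)
    lun <- assembleUnitigs(lg, lone)
    expect_identical(unname(lun$unitigs), unname(lone))
})

test_that("unstranded unitigs are emitted once, in a canonical orientation", {
    set.seed(67)
    tx <- rseq(1200)
    seqs <- c(r1 = substr(tx, 1, 600), r2 = rcOracle(substr(tx, 301, 900)),
              r3 = substr(tx, 601, 1200))
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = FALSE))
    g <- transitiveReduce(buildOverlapGraph(ov, seqs, stranded = FALSE))
    un <- assembleUnitigs(g, seqs)
    expect_identical(length(un$unitigs), 1L)
    expect_true(unname(un$unitigs) %in% c(tx, rcOracle(tx)))

    ## every vertex lands in exactly one unitig path (mirror-collapsed)
    used <- unlist(un$paths)
    baseIds <- substr(used, 1, nchar(used) - 1)
    expect_setequal(baseIds, names(seqs))
    expect_identical(anyDuplicated(baseIds), 0L)
})

test_that("GFA export writes S and L lines for the graph", {
    set.seed(68)
    s <- rseq(900)
    seqs <- c(a = substr(s, 1, 600), b = substr(s, 301, 900))
    ov <- classifyOverlaps(findReadOverlaps(seqs, minOverlap = 150,
                                            stranded = TRUE))
    g <- buildOverlapGraph(ov, seqs, stranded = TRUE)
    path <- tempfile(fileext = ".gfa")
    writeGFA(g, seqs, path)
    lines <- readLines(path)
    expect_identical(sum(startsWith(lines, "S")), 2L)
    expect_identical(sum(startsWith(lines, "L")), nrow(graphEdges(g)))
})
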