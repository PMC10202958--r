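test_that("tiling covers the read contiguously, with and without an offset", {
    expect_identical(tileRead(1200, 500, 0),
                     data.frame(start = c(0L, 500L, 1000L),
                                end = c(500L, 1000L, 1200L)))
    expect_identical(tileRead(1200, 500, 250),
                     data.frame(start = c(0L, 250L, 750L),
                                end = c(250L, 750L, 1200L)))
    expect_identical(tileRead(300, 500, 0),
                     data.frame(start = 0L, end = 300L))
    expect_error(tileRead(0, 500, 0), "positive")
})

test_that("dynamic threshold separates the error mode from coverage modes", {
    expect_identical(dynamicThreshold(rep(1L, 50)), 2L)  # all weak

    ## high coverage with a sprinkle of singleton errors: the ten 1's and
    ## only they fall below the threshold
    m <- c(rep(20L, 90), rep(1L, 10))
    t <- dynamicThreshold(m)
    expect_identical(sum(m < t), 10L)
    expect_identical(sum(m >= t), 90L)

    ## mixed-expression tile: threshold must not split the two coverage modes
    expect_identical(dynamicThreshold(c(1L, 1L, 3L, 3L, 3L, 40L, 40L)), 2L)
})

test_that("correctTile replaces an anchored weak run with the solid path", {
    set.seed(21)
    tx <- rseq(120)
    g <- buildKmerGraph(rep(tx, 20), k = 15, canonical = FALSE)
    cfg <- correctionParams(k = 15, tileLength = 500)

    ## clean tile: returned verbatim, not modified
    res0 <- correctTile(tx, g, cfg)
    expect_identical(res0$seq, tx)
    expect_false(res0$modified)

    ## one substitution mid-tile: corrected to the truth
    bad <- tx
    orig <- substr(bad, 60, 60)
    substr(bad, 60, 60) <- setdiff(c("A", "C", "G", "T"), orig)[1]
    res1 <- correctTile(bad, g, cfg)
    expect_identical(res1$seq, tx)
    expect_true(res1$modified)

    ## identity gate: a corrupted stretch whose solid replacement shares
    ## < 70% identity is left untouched at the default, edited when the
    ## gate is relaxed
    bad2 <- paste0(substr(tx, 1, 49), rseq(30), substr(tx, 80, 120))
    res2 <- correctTile(bad2, g, cfg)
    expect_identical(res2$seq, bad2)
    expect_false(res2$modified)
    resLax <- correctTile(bad2, g, correctionParams(k = 15, tileLength = 500,
                                                    minPathIdentity = 0.2))
    expect_true(resLax$modified)
    expect_identical(resLax$seq, tx)
})

test_that("correctRead iterates with half-shifted tiles and filters junk", {
    set.seed(22)
    tx <- rseq(120)
    g <- buildKmerGraph(rep(tx, 20), k = 15, canonical = FALSE)
    cfg <- correctionParams(k = 15, tileLength = 60)

    ## error-free read is a fixed point
    res <- correctRead(tx, g, cfg)
    expect_false(res$discarded)
    expect_identical(res$seq, tx)

    ## two substitutions, one straddling the offset-0 tile boundary: fully
    ## corrected only thanks to the half-shifted second iteration
    bad <- tx
    for (pos in c(26, 60)) {
        orig <- substr(bad, pos, pos)
        substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "T"), orig)[1]
    }
    res2 <- correctRead(bad, g, cfg)
    expect_identical(res2$seq, tx)
    expect_gte(res2$iterations, 2L)

    ## singleton junk read: all k-mers multiplicity <= 1 in its own graph
    junk <- rseq(200)
    gJunk <- buildKmerGraph(c(rep(tx, 20), junk), k = 15, canonical = FALSE)
    resJ <- correctRead(junk, gJunk, cfg)
    expect_true(resJ$discarded)
    expect_identical(resJ$reason, "low_solid_fraction")

    ## read shorter than k
    resS <- correctRead("ACGTACGT", g, cfg)
    expect_true(resS$discarded)
    expect_identical(resS$reason, "shorter_than_k")
})

test_that("correction lowers the measured error rate and is idempotent", {
    for (seed in 1:2) {
        cfg <- simParams(nGenes = 4, isoformsPerGene = c(1, 1),
                         subRate = 0.03, insRate = 0, delRate = 0,
                         polyALength = c(0, 0), chimeraRate = 0,
                         stranded = TRUE, fullLengthProb = 1, seed = seed)
        txome <- simTranscriptome(cfg)
        rd <- simReads(txome$reference, cfg, nReads = 80,
                       expression = setNames(rep(1, length(txome$reference)),
                                             names(txome$reference)))
        reads <- setNames(rd$reads$seq, rd$reads$id)
        truthTx <- setNames(rd$truth$transcript_id, rd$truth$read_id)
        pre <- errorRateOracle(reads, truthTx[names(reads)], txome$reference)
        cor <- correctReads(reads, canonical = FALSE)
        post <- errorRateOracle(cor$reads, truthTx[names(cor$reads)],
                                txome$reference)
        expect_lt(post, pre)

        ## idempotence: a second pass over the same graph changes nothing
        again <- vapply(names(cor$reads), function(id)
            correctRead(cor$reads[[id]], cor$graph)$seq, character(1))
        expect_identical(unname(again), unname(cor$reads))
    }
})

test_that("positions covered only by solid k-mers are never edited", {
    set.seed(23)
    tx <- rseq(400)
    g <- buildKmerGraph(rep(tx, 20), k = 15, canonical = FALSE)
    cfg <- correctionParams(k = 15, tileLength = 200)
    bad <- tx
    substr(bad, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                     substr(bad, 200, 200))[1]
    res <- correctRead(bad, g, cfg)
    ## bases far from the weak run are byte-identical before/after
    expect_identical(substr(res$seq, 1, 150), substr(bad, 1, 150))
    expect_identical(substr(res$seq, 250, 400), substr(bad, 250, 400))
})
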