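test_that("contigs are gated and assigned, with the truth-preferring tie rule", {
    mkAln <- function(cid, tx, qs, qe, ts, te, ident, indel = 0L,
                      txlen = 1000L)
        data.frame(query_id = cid, query_len = 1000L, query_start = qs,
                   query_end = qe, strand = "+", target_start = ts,
                   target_end = te, matching_bases = round((te - ts) * ident),
                   block_len = te - ts, identity = ident,
                   largest_indel = indel, transcript_id = tx,
                   transcript_len = txlen, stringsAsFactors = FALSE)

    ## clean single-transcript hit -> TP candidate
    a1 <- mkAln("c1", "t1", 0L, 990L, 0L, 990L, 0.99)
    out1 <- filterAndAssign(a1, truthIds = "t1")
    expect_identical(out1$category, "TP")
    expect_identical(out1$transcript_id, "t1")

    ## split alignments to transcripts of different genes -> intergenic MA
    a2 <- rbind(mkAln("c2", "t1", 0L, 500L, 0L, 500L, 0.99),
                mkAln("c2", "t2", 500L, 1000L, 0L, 500L, 0.99))
    out2 <- filterAndAssign(a2, truthIds = c("t1", "t2"),
                            geneMap = c(t1 = "g1", t2 = "g2"))
    expect_identical(out2$category, "MA_inter")
    out2b <- filterAndAssign(a2, truthIds = c("t1", "t2"),
                             geneMap = c(t1 = "g1", t2 = "g1"))
    expect_identical(out2b$category, "MA_intra")

    ## equal-scoring truth and non-truth targets resolve to the truth set
    a3 <- rbind(mkAln("c3", "tTrue", 0L, 900L, 0L, 900L, 0.99),
                mkAln("c3", "tFalse", 0L, 900L, 0L, 900L, 0.99))
    out3 <- filterAndAssign(a3, truthIds = "tTrue")
    expect_identical(out3$transcript_id, "tTrue")
    expect_identical(out3$category, "TP")

    ## large-indel and unclassified calls
    a4 <- mkAln("c4", "t1", 0L, 900L, 0L, 900L, 0.99, indel = 80L)
    expect_identical(filterAndAssign(a4, "t1")$category, "LI")
    a5 <- mkAln("c5", "t1", 0L, 900L, 0L, 900L, 0.80)
    expect_identical(filterAndAssign(a5, "t1")$category, "UC")
})

test_that("reconstruction levels follow the covered fraction cutoffs", {
    aln <- data.frame(query_id = c("c1", "c2", "c2"), query_len = 1000L,
                      query_start = 0L, query_end = 500L, strand = "+",
                      target_start = c(0L, 0L, 200L),
                      target_end = c(960L, 250L, 400L),
                      matching_bases = 500L, block_len = 500L,
                      identity = 0.99, largest_indel = 0L,
                      transcript_id = c("tA", "tB", "tB"),
                      transcript_len = 1000L, stringsAsFactors = FALSE)
    asg <- data.frame(contig_id = c("c1", "c2"), category = "TP",
                      transcript_id = c("tA", "tB"),
                      stringsAsFactors = FALSE)
    lev <- reconstructionLevels(asg, aln, c("tA", "tB", "tC"))
    expect_identical(lev$level, c("complete", "partial", "missing"))
    expect_equal(lev$covered_fraction, c(0.96, 0.4, 0))
    ## union, not sum: c2's overlapping intervals count once
    expect_identical(nrow(lev), 3L)
})

test_that("metric formulas reproduce the definitions on random count vectors", {
    r <- computeMetrics(c(complete = 8, partial = 0, missing = 2, FP = 0,
                          MA_intra = 0, MA_inter = 1, LI = 1, UC = 0,
                          contigs_tp = 12))
    expect_equal(r@F1, 8 / (8 + 0.5 * (2 + 2)))
    expect_equal(r@FDR, 2 / (2 + 8))
    expect_equal(r@redundancy, 12 / 8)
    expect_equal(r@recall, 80)

    set.seed(91)
    for (i in 1:20) {
        x <- c(complete = sample(0:20, 1), partial = sample(0:10, 1),
               missing = sample(0:10, 1), FP = sample(0:5, 1),
               MA_intra = sample(0:5, 1), MA_inter = sample(0:5, 1),
               LI = sample(0:5, 1), UC = sample(0:5, 1))
        x <- c(x, contigs_tp = unname(x["complete"] + x["partial"]) +
                   sample(0:5, 1))
        TP <- x[["complete"]] + x[["partial"]]
        FD <- x[["FP"]] + x[["MA_intra"]] + x[["MA_inter"]] + x[["LI"]] +
            x[["UC"]]
        FN <- x[["missing"]]
        if (TP + FD == 0 || TP == 0) next
        r <- computeMetrics(x)
        expect_equal(r@FDR, FD / (FD + TP))
        expect_equal(r@F1, TP / (TP + 0.5 * (FD + FN)))
        expect_equal(r@recall, 100 * TP / (TP + FN))
        expect_equal(r@redundancy, x[["contigs_tp"]] / TP)
    }
    expect_error(computeMetrics(c(complete = 1)), "missing counts")
})

test_that("a perfect assembly scores recall 100, FDR 0, redundancy 1", {
    set.seed(92)
    reference <- setNames(vapply(1:5, function(i) rseq(800), character(1)),
                          paste0("t", 1:5))
    ev <- evaluateAssembly(setNames(reference, paste0("contig", 1:5)),
                           reference, truthIds = names(reference))
    expect_equal(ev$report@recall, 100)
    expect_equal(ev$report@FDR, 0)
    expect_equal(ev$report@F1, 1.0)
    expect_equal(ev$report@redundancy, 1.0)
    ## complete + partial + missing always equals the truth-set size
    expect_identical(nrow(ev$levels), 5L)

    ## metrics are permutation-invariant in contig order
    ev2 <- evaluateAssembly(setNames(rev(reference), paste0("contig", 5:1)),
                            reference, truthIds = names(reference))
    expect_equal(ev2$report@counts, ev$report@counts)

    expect_error(evaluateAssembly(reference[1], reference,
                                  truthIds = "absent"), "absent")
})
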