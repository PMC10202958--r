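test_that("randstrobe anchors are counted and deterministic", {
    p <- strobemerParams()   # ell 10, windows [15,50), order 3
    set.seed(31)
    s <- rseq(10 + 2 * 50)   # exactly one valid anchor
    st <- randstrobes(s, p)
    expect_identical(nrow(st), 1L)
    expect_identical(st$start, 0L)

    long <- rseq(500)
    st1 <- randstrobes(long, p)
    st2 <- randstrobes(long, p)
    expect_identical(st1, st2)                       # determinism
    expect_gt(nrow(st1), 300)
    expect_identical(nrow(randstrobes(rseq(100), p)), 0L)  # too short
})

test_that("a single substitution preserves at least half the strobemer hashes", {
    set.seed(32)
    p <- strobemerParams()
    s <- rseq(500)
    ## substitute inside the second strobe's selection window of mid anchors
    mut <- s
    substr(mut, 250, 250) <- setdiff(c("A", "C", "G", "T"),
                                     substr(s, 250, 250))[1]
    a <- randstrobes(s, p)
    b <- randstrobes(mut, p)
    shared <- sum(a$hash == b$hash[match(a$start, b$start)], na.rm = TRUE)
    expect_gte(shared / nrow(a), 0.5)
})

test_that("read representation follows interval cover at the target depth", {
    p <- strobemerParams()
    cfgN <- normalizationParams()   # depth 3, margin 50
    set.seed(33)
    read <- rseq(400)
    counter <- strobemerCounter(1e5)
    expect_identical(classifyReadRepresentation(read, counter, cfgN, p),
                     "NOT_REPRESENTED")              # fresh counter

    ## add the same read three times -> every strobemer at depth 3
    for (i in 1:3) {
        st <- randstrobes(read, p)
        .cbf_add_hashes(counter@ptr, st$hash, 1L, 0L)
    }
    expect_identical(classifyReadRepresentation(read, counter, cfgN, p,
                                                stranded = TRUE),
                     "REPRESENTED")

    ## a read sharing only its first half stays unrepresented
    read2 <- paste0(substr(read, 1, 200), rseq(200))
    expect_identical(classifyReadRepresentation(read2, counter, cfgN, p,
                                                stranded = TRUE),
                     "NOT_REPRESENTED")
})

test_that("digital normalization keeps exactly the target depth of duplicates", {
    set.seed(34)
    read <- rseq(400)
    reads <- setNames(rep(read, 10), paste0("r", 1:10))
    res <- digitalNormalize(reads, stranded = TRUE)
    expect_identical(length(res$reads), 3L)
    expect_identical(unname(res$reads), rep(read, 3))  # verbatim

    ## five mutually dissimilar reads are all retained
    dis <- setNames(vapply(1:5, function(i) rseq(400), character(1)),
                    paste0("d", 1:5))
    expect_identical(length(digitalNormalize(dis, stranded = TRUE)$reads), 5L)

    ## empty input
    expect_identical(length(digitalNormalize(character())$reads), 0L)
})

test_that("every dropped read is strobemer-covered by the retained set", {
    p <- strobemerParams()
    cfgN <- normalizationParams()
    set.seed(35)
    tx <- rseq(1200)
    ## 20 staggered 3'-anchored truncations of one transcript
    lens <- sort(round(runif(20, 400, 1200)), decreasing = TRUE)
    reads <- setNames(vapply(lens, function(L)
        substr(tx, 1200 - L + 1, 1200), character(1)), paste0("r", 1:20))
    res <- digitalNormalize(reads, cfgN, p, stranded = TRUE)
    expect_true(reads[which.max(nchar(reads))] %in% res$reads)

    ## recount strobemers over the retained set only, then check cover
    counter <- strobemerCounter(1e5)
    for (r in res$reads) {
        st <- randstrobes(r, p)
        if (nrow(st)) .cbf_add_hashes(counter@ptr, st$hash, 1L, 0L)
    }
    dropped <- setdiff(names(reads), names(res$reads))
    for (id in dropped) {
        expect_identical(
            classifyReadRepresentation(reads[[id]], counter, cfgN, p,
                                       stranded = TRUE),
            "REPRESENTED")
    }
})

test_that("raising the target depth never shrinks the retained set", {
    set.seed(36)
    tx <- rseq(900)
    reads <- setNames(c(
        vapply(1:8, function(i) substr(tx, sample(1:200, 1), 900),
               character(1)),
        vapply(1:4, function(i) rseq(500), character(1))),
        paste0("r", 1:12))
    sizes <- vapply(1:4, function(d)
        length(digitalNormalize(reads, normalizationParams(targetDepth = d),
                                stranded = TRUE)$reads), integer(1))
    expect_true(all(diff(sizes) >= 0))
})
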