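pc <- defaultPrimerConfig()
fuse <- function(target, ssu, p = pc)
    paste0(p@forward, target, p@bridge, ssu, p@reverse)

mutateAt <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    paste(ch, collapse = "")
}

test_that("error-free fused reads split into their exact ground-truth
           spans", {
    target <- "ACGTACGTAACCGGTT"
    ssu <- "TTGGCCAATTGGCCAATACGT"
    sp <- splitFusedReads(Biostrings::DNAStringSet(
        c(r = fuse(target, ssu))), pc)
    expect_identical(sp$status, "ok")
    expect_identical(unname(as.character(sp$target)), target)
    expect_identical(unname(as.character(sp$ssu)), ssu)
    # reconstruction: fragments plus located anchors reproduce the input
    expect_identical(fuse(as.character(sp$target),
                          as.character(sp$ssu)),
                     fuse(target, ssu))
})

test_that("reads lacking an anchor are rejected with a reason", {
    target <- "ACGTACGTAACCGGTT"
    ssu <- "TTGGCCAATTGGCCAA"
    unfused <- paste0(pc@forward, target, pc@reverse)
    sp <- splitFusedReads(Biostrings::DNAStringSet(unfused), pc)
    expect_identical(sp$status, "no_bridge")
    expect_identical(length(sp$target), 0L)
    noFwd <- paste0(target, pc@bridge, ssu, pc@reverse)
    expect_identical(splitFusedReads(
        Biostrings::DNAStringSet(noFwd), pc)$status, "no_forward")
    noRev <- paste0(pc@forward, target, pc@bridge, ssu)
    expect_identical(splitFusedReads(
        Biostrings::DNAStringSet(noRev), pc)$status, "no_reverse")
})

test_that("the per-primer mismatch budget is exact at the boundary", {
    target <- "ACGTACGTAACCGGTTAACC"
    ssu <- "TTGGCCAATTGGCCAATTAA"
    mm <- pc@maxMismatches
    # bridge with exactly maxMismatches substitutions is still found
    bridged <- mutateAt(pc@bridge, seq_len(mm))
    read <- paste0(pc@forward, target, bridged, ssu, pc@reverse)
    sp <- splitFusedReads(Biostrings::DNAStringSet(read), pc)
    expect_identical(sp$status, "ok")
    expect_identical(unname(as.character(sp$ssu)), ssu)
    # cross-check the located window with the brute-force Hamming oracle
    mmProfile <- oracleHammingSearch(pc@bridge, read)
    expect_identical(min(mmProfile), mm)
    # one extra substitution exceeds the budget
    bridgedBad <- mutateAt(pc@bridge, seq_len(mm + 1))
    readBad <- paste0(pc@forward, target, bridgedBad, ssu, pc@reverse)
    expect_identical(splitFusedReads(
        Biostrings::DNAStringSet(readBad), pc)$status, "no_bridge")
    expect_gt(min(oracleHammingSearch(pc@bridge, readBad)), mm)
})

test_that("the leftmost best-scoring window wins", {
    target <- "ACGTACGTAACCGGTTAACC"
    ssu <- "TTGGCCAATTGGCCAATTAA"
    # a 1-mismatch bridge copy sits inside the target, an exact copy
    # later: the exact (best-scoring) hit must anchor the split
    decoy <- mutateAt(pc@bridge, 5)
    read <- paste0(pc@forward, "AAAA", decoy, target, pc@bridge, ssu,
                   pc@reverse)
    sp <- splitFusedReads(Biostrings::DNAStringSet(read), pc)
    expect_identical(sp$status, "ok")
    expect_identical(unname(as.character(sp$ssu)), ssu)
    expect_identical(unname(as.character(sp$target)),
                     paste0("AAAA", decoy, target))
    # two equal-score (exact) copies: the leftmost anchors the split,
    # so everything up to the reverse primer lands in the 16S fragment
    read2 <- paste0(pc@forward, target, pc@bridge, ssu, pc@bridge, ssu,
                    pc@reverse)
    sp2 <- splitFusedReads(Biostrings::DNAStringSet(read2), pc)
    expect_identical(unname(as.character(sp2$target)), target)
    expect_identical(unname(as.character(sp2$ssu)),
                     paste0(ssu, pc@bridge, ssu))
    mmProfile <- oracleHammingSearch(pc@bridge, read2)
    hits <- which(mmProfile == 0)
    expect_length(hits, 2L)
})

test_that("splitting agrees with the Hamming oracle on noisy reads", {
    set.seed(13)
    bases <- c("A", "C", "G", "T")
    for (i in 1:20) {
        target <- paste(sample(bases, 40, TRUE), collapse = "")
        ssu <- paste(sample(bases, 60, TRUE), collapse = "")
        read <- fuse(target, ssu)
        # sprinkle up to maxMismatches errors into each primer region
        nerr <- sample(0:pc@maxMismatches, 1)
        if (nerr > 0) {
            pos <- c(sample(nchar(pc@forward), 1),
                     nchar(pc@forward) + 40 +
                         sample(nchar(pc@bridge), 1))
            read <- mutateAt(read, pos)
        }
        sp <- splitFusedReads(Biostrings::DNAStringSet(read), pc)
        expect_identical(sp$status, "ok")
        expect_identical(unname(as.character(sp$ssu)), ssu)
    }
})
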