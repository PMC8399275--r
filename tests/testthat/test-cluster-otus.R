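randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

test_that("dereplication groups exact duplicates with deterministic
           ordering", {
    u <- dereplicate(c("AAA", "AAA", "CCC"))
    expect_identical(unname(as.character(u)), c("AAA", "CCC"))
    expect_identical(names(u), c("uniq1;size=2", "uniq2;size=1"))
    expect_identical(S4Vectors::mcols(u)$abundance, c(2L, 1L))
    # all-distinct input: abundance 1, lexicographic order
    u2 <- dereplicate(c("TTT", "AAA", "GGG"))
    expect_identical(unname(as.character(u2)), c("AAA", "GGG", "TTT"))
    expect_identical(S4Vectors::mcols(u2)$abundance, c(1L, 1L, 1L))
    expect_identical(length(dereplicate(character(0))), 0L)
    # input order never matters
    set.seed(3)
    reads <- sample(rep(c("ACGT", "TTTT", "GGGG"), c(4, 4, 2)))
    expect_identical(unname(as.character(dereplicate(reads))),
                     c("ACGT", "TTTT", "GGGG"))
})

test_that("global-alignment identity matches the DP oracle", {
    set.seed(5)
    x <- randSeq(100)
    y <- x
    substr(y, 50, 50) <- if (substr(x, 50, 50) == "A") "C" else "A"
    expect_identical(alignmentIdentity(x, x), 1)
    expect_equal(alignmentIdentity(x, y), 0.99)
    expect_equal(oracleAlignmentIdentity(x, y), 0.99)
    # lightly substituted pairs: the diagonal alignment is optimal and
    # identity equals the matching fraction
    for (i in 1:5) {
        a <- randSeq(60)
        k <- sample(1:3, 1)
        b <- a
        for (p in sample(60, k))
            substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(a, p, p))[1]
        expect_equal(alignmentIdentity(a, b), (60 - k) / 60)
        expect_equal(oracleAlignmentIdentity(a, b), (60 - k) / 60)
    }
    # heavily substituted pairs: gapped alignments may score better, but
    # the implementation must agree with the independent DP oracle and
    # never fall below the ungapped matching fraction
    for (i in 1:5) {
        a <- randSeq(60)
        k <- sample(10:25, 1)
        b <- a
        for (p in sample(60, k))
            substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(a, p, p))[1]
        expect_equal(alignmentIdentity(a, b),
                     oracleAlignmentIdentity(a, b), tolerance = 1e-12)
        expect_gte(alignmentIdentity(a, b), (60 - k) / 60)
    }
})

test_that("greedy clustering reproduces the designed three-sequence
           case", {
    set.seed(11)
    X <- randSeq(100)
    Y <- X
    substr(Y, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                 substr(X, 40, 40))[1]
    Z <- X
    for (p in sample(100, 40))  # 60% identity to X
        substr(Z, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(X, p, p))[1]
    expect_equal(oracleAlignmentIdentity(X, Y), 0.99)
    expect_lte(oracleAlignmentIdentity(X, Z), 0.65)
    u <- dereplicate(rep(c(X, Y, Z), c(10, 5, 4)))
    cl <- clusterOTUs(u, identityThreshold = 0.97, minsize = 2)
    expect_identical(unname(as.character(cl$centroids)), c(X, Z))
    m <- cl$membership
    expect_identical(m$otu[m$sequence == Y],
                     m$otu[m$sequence == X])
    expect_identical(S4Vectors::mcols(cl$centroids)$size, c(15L, 4L))
})

test_that("minsize gates centroid founding and unsorted input errors", {
    u <- dereplicate(c("ACGTACGTAC", "TGCATGCATG"))  # two singletons
    cl <- clusterOTUs(u, identityThreshold = 0.97, minsize = 2)
    expect_identical(length(cl$centroids), 0L)
    expect_true(all(is.na(cl$membership$otu)))
    # a single sequence of abundance >= 2 founds its own centroid
    u2 <- dereplicate(rep("ACGTACGTAC", 3))
    cl2 <- clusterOTUs(u2)
    expect_identical(unname(as.character(cl2$centroids)), "ACGTACGTAC")
    bad <- Biostrings::DNAStringSet(c("AAA", "CCC"))
    S4Vectors::mcols(bad) <- S4Vectors::DataFrame(abundance = c(1L, 5L))
    expect_error(clusterOTUs(bad), "sorted")
    expect_error(clusterOTUs(Biostrings::DNAStringSet("AAA")),
                 "abundance")
})

test_that("clustering is invariant to permutations of equal-abundance
           input reads", {
    set.seed(21)
    seqs <- replicate(6, randSeq(50))
    reads <- rep(seqs, times = c(5, 5, 3, 3, 2, 1))
    base <- clusterOTUs(dereplicate(reads))
    for (i in 1:5) {
        perm <- clusterOTUs(dereplicate(sample(reads)))
        expect_identical(as.character(perm$centroids),
                         as.character(base$centroids))
        expect_identical(perm$membership, base$membership)
    }
})

test_that("read mapping assigns by best identity with conservation", {
    set.seed(31)
    c1 <- randSeq(80)
    c2 <- randSeq(80)
    centroids <- Biostrings::DNAStringSet(c(OTU1 = c1, OTU2 = c2))
    near1 <- c1
    substr(near1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(c1, 10, 10))[1]
    far <- randSeq(80)
    reads <- c(c1, near1, c2, far)
    mp <- mapReads(reads, centroids, identityThreshold = 0.97)
    expect_identical(mp$assignments, c("OTU1", "OTU1", "OTU2", NA))
    expect_identical(unname(mp$counts), c(2L, 1L))
    expect_identical(sum(mp$counts) + mp$nUnassigned, length(reads))
    # a read equidistant to two centroids goes to the first
    tie <- mapReads(c1, Biostrings::DNAStringSet(
        c(OTUa = c1, OTUb = c1)), 0.97)
    expect_identical(tie$assignments, "OTUa")
    expect_error(mapReads(reads, Biostrings::DNAStringSet()), "non-empty")
})
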