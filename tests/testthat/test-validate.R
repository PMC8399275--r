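dmFrom <- function(rows, design = referenceDesign()) {
    us <- usableReplicates(design)
    m <- matrix(0L, length(rows), nrow(us),
                dimnames = list(names(rows), us$replicateId))
    for (otu in names(rows)) m[otu, rows[[otu]]] <- 1L
    DetectionMatrix(m, design)
}

test_that("detection probabilities follow the combination arithmetic", {
    dm <- dmFrom(list(OTU1 = c("A1", "B1", "C1")))
    r <- validateStrategy(dm, "biological:3/3")
    expect_identical(nCombinations(r), 9L)
    expect_equal(unname(detectionProbabilities(r)), 1 / 9)
    expect_identical(validatedOTUs(r), "OTU1")
    # one of the 3 + 3 pooled technical pairs
    dm2 <- dmFrom(list(OTU1 = c("A1", "A2")))
    r2 <- validateStrategy(dm2, "technical:2/2")
    expect_identical(nCombinations(r2), 6L)
    expect_equal(unname(detectionProbabilities(r2)), 1 / 6)
    expect_equal(unname(r2@perBatch$A), 1 / 3)
    expect_equal(unname(r2@perBatch$B), 0)
    # a single detection never validates k >= 2 strategies
    dm3 <- dmFrom(list(OTU1 = "A1"))
    for (s in c("technical:2/2", "technical:2/3", "technical:3/3",
                "biological:2/2", "biological:2/3", "biological:3/3")) {
        r3 <- validateStrategy(dm3, s)
        expect_identical(unname(detectionProbabilities(r3)), 0)
        expect_length(validatedOTUs(r3), 0)
    }
})

test_that("probabilities equal the exhaustive enumeration oracle", {
    set.seed(23)
    d <- referenceDesign()
    for (i in 1:30) {
        D <- randomDetectionMatrix(designTable(d), nOTUs = 12, p = 0.4)
        dm <- DetectionMatrix(D, d)
        for (mode in c("technical", "biological"))
            for (kn in list(c(2, 2), c(2, 3), c(3, 3))) {
                got <- detectionProbabilities(validateStrategy(
                    dm, Strategy(mode, kn[1], kn[2])))
                want <- oracleProbabilities(D, designTable(d), mode,
                                            kn[1], kn[2])
                expect_equal(got, want)
            }
    }
})

test_that("relaxing k never loses OTUs and 2/3 dominates 2/2
           probabilities", {
    set.seed(29)
    d <- referenceDesign()
    for (i in 1:30) {
        dm <- DetectionMatrix(
            randomDetectionMatrix(designTable(d), nOTUs = 20, p = 0.35),
            d)
        for (mode in c("technical", "biological")) {
            v22 <- validateStrategy(dm, Strategy(mode, 2, 2))
            v23 <- validateStrategy(dm, Strategy(mode, 2, 3))
            v33 <- validateStrategy(dm, Strategy(mode, 3, 3))
            expect_true(all(validatedOTUs(v33) %in% validatedOTUs(v23)))
            expect_true(all(validatedOTUs(v33) %in% validatedOTUs(v22)))
            # duplicate rules with either denominator validate the same
            # OTU patterns
            expect_identical(sort(validatedOTUs(v23)),
                             sort(validatedOTUs(v22)))
            expect_true(all(detectionProbabilities(v23) >=
                            detectionProbabilities(v22)))
        }
    }
})

test_that("full-biological validation has a closed-form
           characterisation", {
    set.seed(37)
    d <- referenceDesign()
    us <- usableReplicates(d)
    for (i in 1:20) {
        D <- randomDetectionMatrix(designTable(d), nOTUs = 15, p = 0.3)
        dm <- DetectionMatrix(D, d)
        v <- validatedOTUs(validateStrategy(dm, "biological:3/3"))
        inEveryBatch <- rownames(D)[vapply(rownames(D), function(otu)
            all(vapply(split(us$replicateId, us$batchId), function(rr)
                any(D[otu, rr] == 1), logical(1))), logical(1))]
        expect_identical(sort(v), sort(inEveryBatch))
    }
})

test_that("detection efficiency accumulates sorted probabilities", {
    dm <- dmFrom(list(OTU1 = c("A1", "B1", "C1"),
                      OTU2 = c("A1", "A2", "A3", "B1", "B2", "B3", "C1")))
    eff <- detectionEfficiency(validateStrategy(dm, "biological:2/2"))
    expect_identical(eff$otu, c("OTU2", "OTU1"))
    expect_equal(eff$cumulative, cumsum(eff$probability))
    expect_equal(attr(eff, "total"), sum(eff$probability))
    # hand arithmetic: probabilities {1.0, 0.5} accumulate to {1.0, 1.5}
    r <- new("StrategyResult", strategy = Strategy("biological", 2, 2),
             nCombinations = 2L,
             probabilities = c(a = 0.5, b = 1.0),
             validated = c("a", "b"), perBatch = list())
    e2 <- detectionEfficiency(r)
    expect_equal(e2$probability, c(1.0, 0.5))
    expect_equal(e2$cumulative, c(1.0, 1.5))
    # degenerate inputs
    r0 <- new("StrategyResult", strategy = Strategy("biological", 2, 2),
              nCombinations = 0L, probabilities = numeric(0),
              validated = character(0), perBatch = list())
    expect_identical(nrow(detectionEfficiency(r0)), 0L)
    r00 <- new("StrategyResult", strategy = Strategy("biological", 2, 2),
               nCombinations = 2L, probabilities = c(a = 0, b = 0),
               validated = character(0), perBatch = list())
    expect_equal(attr(detectionEfficiency(r00), "total"), 0)
})

test_that("confidence levels follow the LC5 > ... > LC1 ranking", {
    lcOf <- function(rows) {
        lc <- assignConfidenceLevels(dmFrom(rows))
        structure(lc$level, names = lc$otu)
    }
    expect_identical(unname(lcOf(list(O = c("A1", "B1", "C1")))), 5L)
    expect_identical(unname(lcOf(list(O = c("A1", "B2")))), 4L)
    expect_identical(unname(lcOf(list(O = c("A1", "A2", "A3")))), 3L)
    expect_identical(unname(lcOf(list(O = c("A1", "A2")))), 2L)
    expect_identical(unname(lcOf(list(O = "A1"))), 1L)
    expect_identical(unname(lcOf(list(O = "C1"))), 1L)
    # full technical triplicate plus one foreign replicate upgrades to
    # the biological-duplicate level, not beyond
    expect_identical(unname(lcOf(list(O = c("A1", "A2", "A3", "B1")))),
                     4L)
    lc <- lcOf(list(O1 = c("A1", "B1", "C1"), O2 = "B2",
                    O3 = c("B1", "B2")))
    expect_identical(lc[c("O1", "O2", "O3")], c(O1 = 5L, O2 = 1L,
                                                O3 = 2L))
})

test_that("strategy overlap reports set-algebra regions", {
    dm <- dmFrom(list(O1 = c("A1", "A2", "A3"),       # technical only
                      O2 = c("A1", "A2", "B1"),       # both
                      O3 = c("A1", "B1"),             # biological only
                      O4 = "C1",                      # neither
                      O5 = c("B1", "B2", "B3"),       # technical only
                      O6 = c("A3", "C1")))            # biological only
    ov <- strategyOverlap(dm, list(tech = "technical:2/2",
                                   bio = "biological:2/2"))
    expect_identical(dim(ov$membership), c(6L, 2L))
    # direct set algebra on the rows
    expect_identical(unname(ov$membership["O1", ]), c(TRUE, FALSE))
    expect_identical(unname(ov$membership["O2", ]), c(TRUE, TRUE))
    expect_identical(unname(ov$membership["O3", ]), c(FALSE, TRUE))
    expect_identical(unname(ov$membership["O4", ]), c(FALSE, FALSE))
    counts <- structure(ov$regions$count, names = ov$regions$pattern)
    expect_identical(counts[["10"]], 2L)  # O1, O5
    expect_identical(counts[["11"]], 1L)  # O2
    expect_identical(counts[["01"]], 2L)  # O3, O6
    expect_identical(counts[["00"]], 1L)  # O4
    expect_identical(sum(counts), 6L)
    # identical strategies: everything in the intersection or outside
    ov2 <- strategyOverlap(dm, list("technical:2/2", "technical:2/3"))
    expect_true(all(ov2$membership[, 1] == ov2$membership[, 2]))
    expect_error(strategyOverlap(dm, list("technical:2/2")), "two")
})
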