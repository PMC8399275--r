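test_that("simulated communities satisfy their construction constraints", {
    cm <- simulateCommunity(10, sigma = 1, nCarriers = 1, f = 0.1,
                            seed = 1)
    tb <- taxonTable(cm)
    expect_equal(sum(tb$abundance), 1, tolerance = 1e-12)
    expect_equal(sum(tb$abundance[tb$carrier]), 0.1, tolerance = 1e-9)
    cm2 <- simulateCommunity(100, sigma = 1.5, nCarriers = 3, f = 1e-4,
                             seed = 7)
    expect_equal(sum(taxonTable(cm2)$abundance[taxonTable(cm2)$carrier]),
                 1e-4, tolerance = 1e-9)
    expect_length(targetFragments(cm2), 3)
    # determinism
    expect_identical(
        as.character(fragments16S(simulateCommunity(10, nCarriers = 1,
                                                    f = 0.1, seed = 1))),
        as.character(fragments16S(cm)))
    expect_false(identical(
        as.character(fragments16S(simulateCommunity(10, nCarriers = 1,
                                                    f = 0.1, seed = 2))),
        as.character(fragments16S(cm))))
})

test_that("16S fragments keep at least 3% pairwise divergence", {
    cm <- simulateCommunity(12, nCarriers = 1, f = 0.01,
                            fragmentLength16S = 100, seed = 3)
    s <- as.character(fragments16S(cm))
    for (i in 1:11) for (j in (i + 1):12) {
        d <- sum(strsplit(s[i], "")[[1]] != strsplit(s[j], "")[[1]])
        expect_gte(d / 100, 0.03)
    }
    # infeasible divergence for many taxa over a tiny fragment
    expect_error(simulateCommunity(30, nCarriers = 1, f = 0.01,
                                   fragmentLength16S = 3, seed = 1),
                 "divergence")
})

test_that("bead loading follows the Poisson occupancy law", {
    cm <- simulateCommunity(20, sigma = 1, nCarriers = 2, f = 0.05,
                            seed = 1)
    bb <- simulateBeadBatch(cm, 1e5, 0.1, seed = 3, batchId = "A")
    ef <- 1 - length(unique(beadCells(bb)$bead)) / 1e5
    # e^-0.1 = 0.90484 within 3 binomial standard errors at n = 1e5
    expect_gte(ef, 0.9021)
    expect_lte(ef, 0.9076)
    # empirical doublet fraction against the pmf, 3 SE Monte-Carlo band
    per <- table(beadCells(bb)$bead)
    p2 <- occupancyPmf(0.1, 2)
    expect_lt(abs(sum(per == 2) / 1e5 - p2),
              3 * sqrt(p2 * (1 - p2) / 1e5))
    # determinism, and near-total emptiness in the lambda -> 0 limit
    bb2 <- simulateBeadBatch(cm, 1e5, 0.1, seed = 3, batchId = "A")
    expect_identical(beadCells(bb2), beadCells(bb))
    tiny <- simulateBeadBatch(cm, 1e4, 1e-9, seed = 1)
    expect_identical(nrow(beadCells(tiny)), 0L)
})

test_that("carrier-positive bead counts match the occupancy model", {
    cm <- simulateCommunity(50, sigma = 1.5, nCarriers = 5, f = 1e-2,
                            seed = 11)
    got <- vapply(1:200, function(s)
        sum(capturedCarriers(
            simulateBeadBatch(cm, 1e5, 0.1, seed = s), cm)$nBeads),
        numeric(1))
    # working approximation: n f (1 - e^-lambda) ~ 95 carrier beads
    expect_lt(abs(mean(got) - 95), 3 * sqrt(95))
    # exact zero-class expectation: n (1 - e^(-lambda f)), tight band on
    # the 200-seed mean
    mu <- 1e5 * (1 - exp(-0.1 * 1e-2))
    expect_lt(abs(mean(got) - mu), 3 * sqrt(mu / 200))
})

test_that("capture gates replicate tables: no capture, no reads", {
    cm <- simulateCommunity(30, sigma = 1, nCarriers = 3, f = 0.05,
                            seed = 2)
    design <- referenceDesign()
    batches <- lapply(batchIds(design), function(b)
        simulateBeadBatch(cm, 5e3, 0.1,
                          seed = match(b, batchIds(design)) + 100,
                          batchId = b))
    st <- simulateReplicateTables(batches, design, cm,
                                  amplificationSuccess = 1,
                                  readsPerPositive = 500, seed = 9)
    cap <- st$truth$capture
    us <- usableReplicates(design)
    for (tx in carrierIds(cm)) for (j in seq_len(nrow(us))) {
        captured <- any(cap$taxon == tx & cap$batchId == us$batchId[j])
        if (captured) {
            # success 1 and deep reads: detected in every usable replicate
            expect_gte(st$counts[tx, us$replicateId[j]], 10)
        } else {
            expect_identical(st$counts[tx, us$replicateId[j]], 0L)
        }
    }
    # counts reconcile with the amplification ground truth
    amp <- st$truth$amplification
    for (i in seq_len(nrow(amp)))
        expect_identical(st$counts[amp$taxon[i], amp$replicateId[i]],
                         amp$reads[i])
    # determinism
    st2 <- simulateReplicateTables(batches, design, cm,
                                   amplificationSuccess = 1,
                                   readsPerPositive = 500, seed = 9)
    expect_identical(st2$counts, st$counts)
    expect_error(
        simulateReplicateTables(batches[1:2], design, cm, seed = 1),
        "not supplied")
})

test_that("technical replicates of a batch agree more than replicates of
           different batches", {
    design <- referenceDesign()
    us <- usableReplicates(design)
    pairs <- utils::combn(seq_len(nrow(us)), 2)
    sameBatch <- us$batchId[pairs[1, ]] == us$batchId[pairs[2, ]]
    within <- between <- numeric(0)
    for (s in 1:30) {
        cm <- simulateCommunity(200, sigma = 1.5, nCarriers = 40,
                                f = 1e-2, seed = s)
        batches <- lapply(batchIds(design), function(b)
            simulateBeadBatch(cm, 2e4, 0.1,
                              seed = s * 10 + match(b, batchIds(design)),
                              batchId = b))
        st <- simulateReplicateTables(batches, design, cm,
                                      amplificationSuccess = 0.8,
                                      readsPerPositive = 10,
                                      seed = s + 500)
        D <- (st$counts >= 10) * 1
        D <- D[rowSums(D) > 0, , drop = FALSE]
        if (nrow(D) < 2) next
        agree <- apply(pairs, 2, function(p)
            mean(D[, us$replicateId[p[1]]] == D[, us$replicateId[p[2]]]))
        within <- c(within, mean(agree[sameBatch]))
        between <- c(between, mean(agree[!sameBatch]))
    }
    expect_gt(mean(within), mean(between))
})
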