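#' One seeded replicate-dependence contrast
#'
#' Runs a single simulated epicPCR experiment — community with rare
#' carriers, Poisson bead loading of one batch per design batch,
#' batch-level carrier capture, amplification dropout, the minimum-read
#' detection rule — and contrasts duplicate- against triplicate-based
#' validation in both modes with McNemar's test. Because technical
#' replicates share their batch's captured carriers while biological
#' replicates re-draw capture, the discordance asymmetry (`b - c`, OTUs
#' validated by duplicates but not triplicates minus the converse) is
#' expected to be systematically larger in technical mode.
#'
#' @param seed Integer seed for this experiment.
#' @param nTaxa,nCarriers,sigma,f Community parameters (see
#'   [simulateCommunity()]); defaults are the package's reference
#'   conditions for rare-carrier experiments.
#' @param nBeads,lambda Bead-batch parameters.
#' @param design A [ReplicateDesign-class].
#' @param amplificationSuccess,readsPerPositive See
#'   [simulateReplicateTables()].
#' @param minReads Detection threshold.
#' @return List with `technical` and `biological`, each holding `b`, `c`,
#'   `asymmetry` (b - c) and `p_value`, plus `nDetected`.
#' @examples
#' dependenceContrast(seed = 1, nBeads = 1e4)
#' @export
dependenceContrast <- function(seed, nTaxa = 1200, nCarriers = 600,
                               sigma = 1.5, f = 1e-2, nBeads = 1e5,
                               lambda = 0.1, design = referenceDesign(),
                               amplificationSuccess = 0.8,
                               readsPerPositive = 10, minReads = 10) {
    cm <- simulateCommunity(nTaxa, sigma = sigma, nCarriers = nCarriers,
                            f = f, seed = deriveSeed(seed, 1L))
    bids <- batchIds(design)
    batches <- lapply(seq_along(bids), function(i)
        simulateBeadBatch(cm, nBeads, lambda,
                          seed = deriveSeed(seed, 10L + i),
                          batchId = bids[i]))
    tabs <- simulateReplicateTables(batches, design, cm,
                                    amplificationSuccess,
                                    readsPerPositive,
                                    seed = deriveSeed(seed, 30L))
    dm <- buildDetectionMatrix(tabs$counts, design, minReads = minReads)
    one <- function(mode) {
        cmp <- compareStrategies(dm, paste0(mode, ":2/2"),
                                 paste0(mode, ":3/3"))
        b <- unname(cmp$test$parameter["b"])
        c <- unname(cmp$test$parameter["c"])
        list(b = b, c = c, asymmetry = b - c,
             p_value = cmp$test$p.value)
    }
    list(technical = one("technical"), biological = one("biological"),
         nDetected = length(detectedOTUs(dm)))
}
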