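#' Simulate a microbial community with rare target carriers
#'
#' Draws lognormal relative abundances for `nTaxa` taxa, flags `nCarriers`
#' of them as target-gene carriers, and rescales abundances so the carriers
#' jointly account for a relative abundance `f` (the regime of interest is
#' rare carriers, `f` down to 1e-7, as for mobile genetic elements counted
#' per 16S rRNA gene copy). Each taxon receives a random 16S fragment;
#' fragments are re-drawn until all pairwise divergences are at least
#' `minDivergence`, so that clustering at the canonical 97\% identity
#' radius separates taxa. Each carrier also receives a target-gene
#' fragment.
#'
#' @param nTaxa Number of taxa.
#' @param sigma Lognormal shape (sdlog) of the abundance distribution.
#' @param nCarriers Number of carrier taxa (`<= nTaxa`).
#' @param f Aggregate carrier relative abundance, in `(0, 1)`.
#' @param fragmentLength16S,fragmentLengthTarget Fragment lengths in bp.
#' @param seed Integer seed; the same seed reproduces the same community.
#' @param minDivergence Minimum pairwise divergence between 16S fragments.
#' @param maxAttempts Regeneration attempts before giving up.
#' @return A [Community-class].
#' @examples
#' simulateCommunity(10, sigma = 1, nCarriers = 1, f = 0.1, seed = 1)
#' @export
simulateCommunity <- function(nTaxa, sigma = 1.5, nCarriers = 1, f = 1e-3,
                              fragmentLength16S = 250,
                              fragmentLengthTarget = 120,
                              seed = 1, minDivergence = 0.03,
                              maxAttempts = 5) {
    nTaxa <- assertCount(nTaxa, "nTaxa", positive = TRUE)
    nCarriers <- assertCount(nCarriers, "nCarriers", positive = TRUE)
    if (nCarriers > nTaxa)
        stop("'nCarriers' must not exceed 'nTaxa'", call. = FALSE)
    assertScalarNumeric(f, "f")
    if (f <= 0 || f >= 1)
        stop("'f' must be in (0, 1)", call. = FALSE)
    withSeed(seed, {
        raw <- stats::rlnorm(nTaxa, meanlog = 0, sdlog = sigma)
        carrier <- logical(nTaxa)
        carrier[sample.int(nTaxa, nCarriers)] <- TRUE
        ab <- raw
        ab[carrier] <- raw[carrier] / sum(raw[carrier]) * f
        ab[!carrier] <- raw[!carrier] / sum(raw[!carrier]) * (1 - f)
        ids <- sprintf("taxon%03d", seq_len(nTaxa))
        frags <- .divergentFragments(nTaxa, fragmentLength16S,
                                     minDivergence, maxAttempts)
        targets <- randomDNA(nCarriers, fragmentLengthTarget)
        s16 <- Biostrings::DNAStringSet(frags)
        names(s16) <- ids
        tg <- Biostrings::DNAStringSet(targets)
        names(tg) <- ids[carrier]
        new("Community",
            taxa = data.frame(id = ids, abundance = ab, carrier = carrier,
                              stringsAsFactors = FALSE),
            fragments16S = s16, targetFragments = tg,
            f = f, seed = as.numeric(seed))
    })
}

# Random fragments with all pairwise divergences >= minDivergence.
# Divergence is checked on the base-index matrix with a per-base
# match-count cross product, so the check is O(nTaxa^2) in matrix algebra.
.divergentFragments <- function(n, len, minDivergence, maxAttempts) {
    bases <- c("A", "C", "G", "T")
    for (attempt in seq_len(maxAttempts)) {
        idx <- matrix(sample.int(4L, n * len, replace = TRUE), nrow = n)
        if (n > 1) {
            matches <- matrix(0, n, n)
            for (b in 1:4) {
                m <- (idx == b) * 1
                matches <- matches + tcrossprod(m)
            }
            diag(matches) <- 0
            if (max(matches) > (1 - minDivergence) * len) next
        }
        return(apply(idx, 1, function(r)
            paste(bases[r], collapse = "")))
    }
    stop("could not generate ", n, " fragments of ", len,
         " bp with pairwise divergence >= ", minDivergence, call. = FALSE)
}

#' Simulate Poisson loading of one bead batch
#'
#' Each of `nBeads` beads receives a Poisson(\eqn{\lambda}) number of
#' cells; cell identities are drawn independently from the community
#' relative abundances. Only occupied beads are stored.
#'
#' @param community A [Community-class].
#' @param nBeads Number of beads (a real experiment rarely exceeds ~3e6).
#' @param lambda Mean occupancy, `> 0`.
#' @param seed Integer seed.
#' @param batchId Batch identifier.
#' @return A [BeadBatch-class].
#' @examples
#' cm <- simulateCommunity(10, nCarriers = 1, f = 0.1, seed = 1)
#' simulateBeadBatch(cm, 1e4, 0.1, seed = 3)
#' @export
simulateBeadBatch <- function(community, nBeads, lambda, seed = 1,
                              batchId = "batch1") {
    stopifnot(is(community, "Community"))
    nBeads <- assertCount(nBeads, "nBeads", positive = TRUE)
    assertScalarNumeric(lambda, "lambda")
    if (lambda <= 0) stop("'lambda' must be > 0", call. = FALSE)
    tb <- taxonTable(community)
    withSeed(seed, {
        counts <- stats::rpois(nBeads, lambda)
        occ <- which(counts > 0L)
        total <- sum(counts)
        taxon <- if (total > 0)
            sample(tb$id, total, replace = TRUE, prob = tb$abundance)
        else character(0)
        cells <- data.frame(
            bead = rep(occ, counts[occ]), taxon = taxon,
            stringsAsFactors = FALSE)
        new("BeadBatch", batchId = as.character(batchId),
            nBeads = nBeads, lambda = as.numeric(lambda),
            cells = cells, seed = as.numeric(seed))
    })
}

#' Empirical bead statistics and quality verdict of a simulated batch
#'
#' Tabulates empty/singleton/multi bead counts of a [BeadBatch-class] and
#' applies [assessBeadBatch()].
#'
#' @param batch A [BeadBatch-class].
#' @inheritParams assessBeadBatch
#' @return A [BeadQCResult-class].
#' @export
beadBatchQC <- function(batch, emptyThreshold = 0.90,
                        singletonThreshold = 0.85) {
    stopifnot(is(batch, "BeadBatch"))
    per <- table(batch@cells$bead)
    nSingle <- sum(per == 1L)
    nMulti <- sum(per > 1L)
    assessBeadBatch(batch@nBeads - nSingle - nMulti, nSingle, nMulti,
                    emptyThreshold, singletonThreshold)
}

#' Carrier taxa captured by a bead batch
#'
#' A carrier taxon is captured when at least one bead of the batch contains
#' one of its cells; only captured carriers can ever yield fused amplicons
#' in the batch's technical replicates (the mechanism that makes technical
#' replicates of one batch dependent).
#'
#' @param batch A [BeadBatch-class].
#' @param community The [Community-class] the batch was drawn from.
#' @return data.frame with columns `taxon` and `nBeads` (number of beads
#'   containing the carrier), one row per captured carrier.
#' @export
capturedCarriers <- function(batch, community) {
    stopifnot(is(batch, "BeadBatch"), is(community, "Community"))
    cells <- batch@cells
    keep <- cells$taxon %in% carrierIds(community)
    if (!any(keep))
        return(data.frame(taxon = character(0), nBeads = integer(0),
                          stringsAsFactors = FALSE))
    cc <- cells[keep, , drop = FALSE]
    # one bead counts once per carrier even if it holds several of its cells
    cc <- unique(cc[, c("bead", "taxon")])
    agg <- table(cc$taxon)
    data.frame(taxon = names(agg), nBeads = as.integer(agg),
               row.names = NULL, stringsAsFactors = FALSE)
}
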