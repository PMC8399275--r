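#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Poisson bead-occupancy model
#'
#' Holds the mean occupancy \eqn{\lambda} (expected cells per polyacrylamide
#' bead). Under Poisson loading with no cell aggregates, the number of cells
#' entrapped in a bead is \eqn{k \sim Poisson(\lambda)}.
#'
#' @slot lambda Non-negative numeric scalar, expected cells per bead.
#' @seealso [occupancyPmf()], [lambdaFromEmptyFraction()]
#' @export
setClass("OccupancyModel", representation(lambda = "numeric"))

setValidity("OccupancyModel", function(object) {
    if (length(object@lambda) != 1L || is.na(object@lambda) ||
        object@lambda < 0)
        return("'lambda' must be a single non-negative number")
    TRUE
})

#' Quality verdict for one bead batch
#'
#' Result of applying the bead-batch quality rules: a batch is usable when
#' more than 90\% of beads are empty and at least 85\% of non-empty beads
#' carry a single cell, so that the probability of target-carrying doublets
#' is negligible.
#'
#' @slot nEmpty,nSingle,nMulti Integer counts of beads with 0, 1, >1 cells.
#' @slot emptyFraction Fraction of empty beads among all beads.
#' @slot singletonFraction Fraction of single-cell beads among non-empty
#'   beads; reported as 1 (with `degenerate = TRUE`) when no bead is
#'   occupied, since there is then no evidence of multi-cell beads.
#' @slot passed Logical verdict.
#' @slot degenerate TRUE when the singleton fraction was undefined.
#' @slot emptyThreshold,singletonThreshold Thresholds used (strict `>` for
#'   empty, inclusive `>=` for singletons).
#' @seealso [assessBeadBatch()]
#' @export
setClass("BeadQCResult", representation(
    nEmpty = "integer", nSingle = "integer", nMulti = "integer",
    emptyFraction = "numeric", singletonFraction = "numeric",
    passed = "logical", degenerate = "logical",
    emptyThreshold = "numeric", singletonThreshold = "numeric"))

#' Simulated microbial community
#'
#' A set of taxa with lognormal relative abundances, a flagged subset of
#' target-carrier taxa whose abundances jointly sum to the carrier frequency
#' `f`, one 16S rRNA gene fragment per taxon and one target-gene fragment
#' per carrier.
#'
#' @slot taxa data.frame with columns `id`, `abundance`, `carrier`.
#' @slot fragments16S Named [Biostrings::DNAStringSet], one per taxon.
#' @slot targetFragments Named [Biostrings::DNAStringSet], one per carrier.
#' @slot f Aggregate carrier relative abundance.
#' @slot seed Seed used to generate the community.
#' @seealso [simulateCommunity()]
#' @export
setClass("Community", representation(
    taxa = "data.frame", fragments16S = "DNAStringSet",
    targetFragments = "DNAStringSet", f = "numeric", seed = "numeric"))

setValidity("Community", function(object) {
    msg <- character()
    if (!all(c("id", "abundance", "carrier") %in% names(object@taxa)))
        msg <- c(msg, "'taxa' needs columns id, abundance, carrier")
    else {
        if (any(object@taxa$abundance < 0))
            msg <- c(msg, "abundances must be non-negative")
        if (abs(sum(object@taxa$abundance) - 1) > 1e-9)
            msg <- c(msg, "abundances must sum to 1")
        fc <- sum(object@taxa$abundance[object@taxa$carrier])
        if (abs(fc - object@f) > 1e-9)
            msg <- c(msg, "'f' must equal the summed carrier abundance")
        if (!setequal(names(object@fragments16S), object@taxa$id))
            msg <- c(msg, "16S fragments must be named by taxon id")
    }
    if (length(msg)) msg else TRUE
})

#' Simulated bead batch
#'
#' One polyacrylamide bead preparation: `nBeads` beads loaded with
#' Poisson(\eqn{\lambda}) cells each, cell identities drawn from the
#' community abundances. Only occupied beads are stored, as a
#' (bead index, taxon id) table.
#'
#' @slot batchId Batch identifier.
#' @slot nBeads Total number of beads (occupied or not).
#' @slot lambda Mean occupancy used.
#' @slot cells data.frame with columns `bead` (integer) and `taxon`.
#' @slot seed Seed used.
#' @seealso [simulateBeadBatch()]
#' @export
setClass("BeadBatch", representation(
    batchId = "character", nBeads = "integer", lambda = "numeric",
    cells = "data.frame", seed = "numeric"))

#' Replicate design of an epicPCR experiment
#'
#' Bead batches and their technical replicates, with a usable flag per
#' replicate (amplifications whose sequencing failed quality requirements
#' are kept in the design but flagged unusable). Technical replicates are
#' repeated amplifications of one batch; biological replicates use
#' different batches.
#'
#' @slot table data.frame with columns `batchId`, `replicateId`, `usable`.
#' @seealso [ReplicateDesign()], [referenceDesign()]
#' @export
setClass("ReplicateDesign", representation(table = "data.frame"))

setValidity("ReplicateDesign", function(object) {
    tb <- object@table
    msg <- character()
    if (!all(c("batchId", "replicateId", "usable") %in% names(tb)))
        msg <- c(msg, "need columns batchId, replicateId, usable")
    else {
        if (anyDuplicated(tb$replicateId))
            msg <- c(msg, "replicate ids must be globally unique")
        if (!any(tb$usable))
            msg <- c(msg, "at least one replicate must be usable")
    }
    if (length(msg)) msg else TRUE
})

#' Primer configuration for fused amplicons
#'
#' Sequences of the three anchors of a fused read, as they appear on the
#' forward strand of the merged amplicon:
#' `[forward][target][bridge][16S][reverse]`. The bridge is the junction
#' created by the fusion primer. A bench reverse primer must therefore be
#' reverse-complemented before being stored here.
#'
#' @slot forward,bridge,reverse Uppercase A/C/G/T/N sequences.
#' @slot maxMismatches Mismatch budget per primer during matching.
#' @seealso [PrimerConfig()], [splitFusedReads()]
#' @export
setClass("PrimerConfig", representation(
    forward = "character", bridge = "character", reverse = "character",
    maxMismatches = "integer"))

setValidity("PrimerConfig", function(object) {
    seqs <- c(object@forward, object@bridge, object@reverse)
    if (any(nchar(seqs) == 0) || any(!grepl("^[ACGTN]+$", seqs)))
        return("primer sequences must be non-empty uppercase A/C/G/T/N")
    if (object@maxMismatches < 0)
        return("'maxMismatches' must be >= 0")
    TRUE
})

#' OTU validation strategy (k-out-of-n replicates)
#'
#' An OTU validates a combination of `n` replicates when detected in at
#' least `k` of them. Technical combinations are drawn within one bead
#' batch; biological combinations take one replicate from each of `n`
#' distinct batches.
#'
#' @slot mode `"technical"` or `"biological"`.
#' @slot k Minimum detections within a combination.
#' @slot n Combination size.
#' @seealso [Strategy()], [validateStrategy()]
#' @export
setClass("Strategy", representation(
    mode = "character", k = "integer", n = "integer"))

setValidity("Strategy", function(object) {
    if (!object@mode %in% c("technical", "biological"))
        return("mode must be 'technical' or 'biological'")
    if (object@k < 1L || object@k > object@n)
        return("need 1 <= k <= n")
    TRUE
})

#' Result of applying a validation strategy
#'
#' @slot strategy The [Strategy-class] applied.
#' @slot nCombinations Number of replicate combinations enumerated.
#' @slot probabilities Named per-OTU detection probability: validating
#'   combinations / all combinations.
#' @slot validated OTU ids with probability > 0.
#' @slot perBatch For technical strategies, per-batch probability matrices.
#' @seealso [validateStrategy()], [detectionEfficiency()]
#' @export
setClass("StrategyResult", representation(
    strategy = "Strategy", nCombinations = "integer",
    probabilities = "numeric", validated = "character", perBatch = "list"))

#' Binary OTU-by-replicate detection matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a `detected` assay
#' (0/1: read count at or above the minimum-read threshold), replicates as
#' columns annotated with their batch, and the threshold in
#' `metadata(x)$minReads`. When built from counts, the `counts` assay is
#' retained.
#'
#' @seealso [buildDetectionMatrix()], [DetectionMatrix()]
#' @export
setClass("DetectionMatrix", contains = "SummarizedExperiment")

setValidity("DetectionMatrix", function(object) {
    if (!"detected" %in% SummarizedExperiment::assayNames(object))
        return("need a 'detected' assay")
    d <- SummarizedExperiment::assay(object, "detected")
    if (!all(d %in% c(0L, 1L)))
        return("'detected' assay must be binary")
    if (!"batchId" %in% names(SummarizedExperiment::colData(object)))
        return("colData needs a 'batchId' column")
    TRUE
})
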