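#' @include AllClasses.R
NULL

#' Accessors for epicpcr2 classes
#'
#' Small accessor generics: `meanOccupancy()` returns \eqn{\lambda};
#' `qcPassed()` the quality verdict; `emptyFraction()` /
#' `singletonFraction()` the bead-class fractions (empirical for a
#' [BeadBatch-class]); `carrierIds()`, `carrierFrequency()`,
#' `fragments16S()`, `targetFragments()` and `taxonTable()` describe a
#' [Community-class]; `beadCells()` the occupied-bead table of a
#' [BeadBatch-class]; `designTable()`, `usableReplicates()` and
#' `batchIds()` a [ReplicateDesign-class]; `detectionProbabilities()`,
#' `validatedOTUs()` and `nCombinations()` a [StrategyResult-class];
#' `minReadsThreshold()` and `replicateBatches()` a
#' [DetectionMatrix-class].
#'
#' @param x An object of the documented class.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meanOccupancy", function(x) standardGeneric("meanOccupancy"))
#' @rdname accessors
#' @export
setGeneric("qcPassed", function(x) standardGeneric("qcPassed"))
#' @rdname accessors
#' @export
setGeneric("emptyFraction", function(x) standardGeneric("emptyFraction"))
#' @rdname accessors
#' @export
setGeneric("singletonFraction",
           function(x) standardGeneric("singletonFraction"))
#' @rdname accessors
#' @export
setGeneric("carrierIds", function(x) standardGeneric("carrierIds"))
#' @rdname accessors
#' @export
setGeneric("carrierFrequency", function(x) standardGeneric("carrierFrequency"))
#' @rdname accessors
#' @export
setGeneric("fragments16S", function(x) standardGeneric("fragments16S"))
#' @rdname accessors
#' @export
setGeneric("targetFragments", function(x) standardGeneric("targetFragments"))
#' @rdname accessors
#' @export
setGeneric("taxonTable", function(x) standardGeneric("taxonTable"))
#' @rdname accessors
#' @export
setGeneric("beadCells", function(x) standardGeneric("beadCells"))
#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setGeneric("usableReplicates", function(x) standardGeneric("usableReplicates"))
#' @rdname accessors
#' @export
setGeneric("batchIds", function(x) standardGeneric("batchIds"))
#' @rdname accessors
#' @export
setGeneric("detectionProbabilities",
           function(x) standardGeneric("detectionProbabilities"))
#' @rdname accessors
#' @export
setGeneric("validatedOTUs", function(x) standardGeneric("validatedOTUs"))
#' @rdname accessors
#' @export
setGeneric("nCombinations", function(x) standardGeneric("nCombinations"))
#' @rdname accessors
#' @export
setGeneric("minReadsThreshold",
           function(x) standardGeneric("minReadsThreshold"))
#' @rdname accessors
#' @export
setGeneric("replicateBatches", function(x) standardGeneric("replicateBatches"))

#' @rdname accessors
setMethod("meanOccupancy", "OccupancyModel", function(x) x@lambda)
#' @rdname accessors
setMethod("meanOccupancy", "BeadBatch", function(x) x@lambda)
#' @rdname accessors
setMethod("qcPassed", "BeadQCResult", function(x) x@passed)
#' @rdname accessors
setMethod("emptyFraction", "BeadQCResult", function(x) x@emptyFraction)
#' @rdname accessors
setMethod("singletonFraction", "BeadQCResult", function(x) x@singletonFraction)
#' @rdname accessors
setMethod("carrierIds", "Community",
          function(x) x@taxa$id[x@taxa$carrier])
#' @rdname accessors
setMethod("carrierFrequency", "Community", function(x) x@f)
#' @rdname accessors
setMethod("fragments16S", "Community", function(x) x@fragments16S)
#' @rdname accessors
setMethod("targetFragments", "Community", function(x) x@targetFragments)
#' @rdname accessors
setMethod("taxonTable", "Community", function(x) x@taxa)
#' @rdname accessors
setMethod("beadCells", "BeadBatch", function(x) x@cells)
#' @rdname accessors
setMethod("designTable", "ReplicateDesign", function(x) x@table)
#' @rdname accessors
setMethod("usableReplicates", "ReplicateDesign",
          function(x) x@table[x@table$usable, , drop = FALSE])
#' @rdname accessors
setMethod("batchIds", "ReplicateDesign", function(x) unique(x@table$batchId))
#' @rdname accessors
setMethod("detectionProbabilities", "StrategyResult",
          function(x) x@probabilities)
#' @rdname accessors
setMethod("validatedOTUs", "StrategyResult", function(x) x@validated)
#' @rdname accessors
setMethod("nCombinations", "StrategyResult", function(x) x@nCombinations)
#' @rdname accessors
setMethod("minReadsThreshold", "DetectionMatrix",
          function(x) metadata(x)$minReads)
#' @rdname accessors
setMethod("replicateBatches", "DetectionMatrix", function(x)
    structure(as.character(SummarizedExperiment::colData(x)$batchId),
              names = colnames(x)))

setMethod("show", "OccupancyModel", function(object) {
    cat("OccupancyModel: lambda =", object@lambda,
        "| P(empty) =", signif(exp(-object@lambda), 5),
        "| P(doublet) =", signif(stats::dpois(2, object@lambda), 5), "\n")
})

setMethod("show", "BeadQCResult", function(object) {
    cat(sprintf(
        "BeadQCResult: %d empty / %d single / %d multi\n",
        object@nEmpty, object@nSingle, object@nMulti))
    cat(sprintf("  empty fraction     %.4f (threshold > %.2f)\n",
                object@emptyFraction, object@emptyThreshold))
    cat(sprintf("  singleton fraction %.4f (threshold >= %.2f)%s\n",
                object@singletonFraction, object@singletonThreshold,
                if (object@degenerate) " [no occupied beads]" else ""))
    cat("  passed:", object@passed, "\n")
})

setMethod("show", "Community", function(object) {
    cat(sprintf(
        "Community: %d taxa, %d carriers (f = %g), 16S %d bp, target %d bp\n",
        nrow(object@taxa), sum(object@taxa$carrier), object@f,
        unique(Biostrings::width(object@fragments16S))[1],
        if (length(object@targetFragments))
            unique(Biostrings::width(object@targetFragments))[1] else 0L))
})

setMethod("show", "BeadBatch", function(object) {
    occ <- length(unique(object@cells$bead))
    cat(sprintf(
        "BeadBatch '%s': %d beads, lambda = %g, %d occupied (empty %.4f)\n",
        object@batchId, object@nBeads, object@lambda, occ,
        1 - occ / object@nBeads))
})

setMethod("show", "ReplicateDesign", function(object) {
    us <- usableReplicates(object)
    cat(sprintf("ReplicateDesign: %d batches, %d replicates (%d usable)\n",
                length(batchIds(object)), nrow(object@table), nrow(us)))
    for (b in batchIds(object)) {
        tb <- object@table[object@table$batchId == b, ]
        cat(sprintf("  %s: %s\n", b, paste0(
            tb$replicateId, ifelse(tb$usable, "", "(x)"), collapse = " ")))
    }
})

setMethod("show", "PrimerConfig", function(object) {
    cat("PrimerConfig (forward strand of the merged amplicon):\n")
    cat("  forward:", object@forward, "\n  bridge: ", object@bridge,
        "\n  reverse:", object@reverse,
        "\n  max mismatches per primer:", object@maxMismatches, "\n")
})

setMethod("show", "Strategy", function(object) {
    cat(sprintf("Strategy: %d/%d %s replicates\n",
                object@k, object@n, object@mode))
})

setMethod("show", "StrategyResult", function(object) {
    show(object@strategy)
    cat(sprintf("  %d combinations, %d/%d OTUs validated (prob > 0)\n",
                object@nCombinations, length(object@validated),
                length(object@probabilities)))
})
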