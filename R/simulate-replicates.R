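#' Simulate per-replicate OTU read-count tables with batch-level capture
#'
#' The dependence mechanism of technical replicates is made explicit: a
#' carrier taxon can yield reads in a technical replicate only if the
#' taxon was encapsulated in that replicate's bead batch. Given capture,
#' each carrier-containing bead amplifies independently in each usable
#' replicate with probability `amplificationSuccess`, and each amplified
#' bead emits a zero-truncated Poisson number of reads with underlying
#' mean `readsPerPositive`. Replicates of different batches are therefore
#' independent, while replicates of one batch share the batch's captured
#' carriers.
#'
#' @param batches List of [BeadBatch-class] objects covering every batch
#'   id in `design`.
#' @param design A [ReplicateDesign-class]; only usable replicates yield
#'   count columns.
#' @param community The [Community-class] the batches were drawn from.
#' @param amplificationSuccess Per-carrier-bead, per-replicate probability
#'   that the fusion amplification succeeds.
#' @param readsPerPositive Underlying Poisson mean read count per
#'   amplified carrier bead.
#' @param seed Integer master seed.
#' @return List with `counts` (integer matrix, carrier taxa x usable
#'   replicates) and `truth`, a list holding the per-batch `capture` table
#'   (batchId, taxon, nBeads) and the per-replicate `amplification` table
#'   (replicateId, batchId, taxon, nPositiveBeads, reads).
#' @examples
#' cm <- simulateCommunity(20, nCarriers = 2, f = 0.05, seed = 1)
#' d <- referenceDesign()
#' bb <- lapply(batchIds(d), function(b)
#'     simulateBeadBatch(cm, 2e4, 0.1, seed = match(b, batchIds(d)),
#'                       batchId = b))
#' st <- simulateReplicateTables(bb, d, cm, seed = 5)
#' head(st$counts)
#' @export
simulateReplicateTables <- function(batches, design, community,
                                    amplificationSuccess = 0.8,
                                    readsPerPositive = 50,
                                    seed = 1) {
    stopifnot(is(design, "ReplicateDesign"), is(community, "Community"))
    ids <- vapply(batches, function(b) b@batchId, character(1))
    names(batches) <- ids
    if (!all(batchIds(design) %in% ids))
        stop("design references batches not supplied: ",
             paste(setdiff(batchIds(design), ids), collapse = ", "),
             call. = FALSE)
    if (amplificationSuccess < 0 || amplificationSuccess > 1)
        stop("'amplificationSuccess' must be in [0, 1]", call. = FALSE)
    us <- usableReplicates(design)
    carriers <- carrierIds(community)
    counts <- matrix(0L, nrow = length(carriers), ncol = nrow(us),
                     dimnames = list(carriers, us$replicateId))
    capture <- do.call(rbind, lapply(batchIds(design), function(b) {
        cc <- capturedCarriers(batches[[b]], community)
        if (nrow(cc)) cbind(batchId = b, cc) else NULL
    }))
    if (is.null(capture))
        capture <- data.frame(batchId = character(0), taxon = character(0),
                              nBeads = integer(0), stringsAsFactors = FALSE)
    amp <- vector("list", nrow(us))
    withSeed(deriveSeed(seed, 211L), {
        for (j in seq_len(nrow(us))) {
            b <- us$batchId[j]
            cap <- capture[capture$batchId == b, , drop = FALSE]
            if (nrow(cap) == 0L) next
            nPos <- stats::rbinom(nrow(cap), cap$nBeads,
                                  amplificationSuccess)
            reads <- vapply(nPos, function(np)
                sum(rztpois(np, readsPerPositive)), numeric(1))
            counts[cap$taxon, j] <- as.integer(reads)
            amp[[j]] <- data.frame(
                replicateId = us$replicateId[j], batchId = b,
                taxon = cap$taxon, nPositiveBeads = nPos,
                reads = as.integer(reads), stringsAsFactors = FALSE)
        }
    })
    amp <- do.call(rbind, amp)
    if (is.null(amp))
        amp <- data.frame(replicateId = character(0), batchId = character(0),
                          taxon = character(0), nPositiveBeads = integer(0),
                          reads = integer(0), stringsAsFactors = FALSE)
    list(counts = counts,
         truth = list(capture = capture, amplification = amp))
}

#' Build a detection matrix from OTU read counts
#'
#' Applies the minimum-read rule: an OTU is detected in a replicate when
#' its read count is at least `minReads`. The default of 10 reads is the
#' epicPCR 2.0 dialect; 100 reproduces the original epicPCR rule.
#'
#' @param counts Integer matrix, OTUs x replicates, with replicate ids as
#'   column names; every column must be a usable replicate of `design`.
#' @param design A [ReplicateDesign-class].
#' @param minReads Minimum read count for detection.
#' @return A [DetectionMatrix-class] carrying `detected` and `counts`
#'   assays, batch annotation, and the threshold in its metadata.
#' @examples
#' d <- referenceDesign()
#' m <- matrix(c(12, 0, 9, 10, 0, 0, 25), 1,
#'             dimnames = list("OTU1", usableReplicates(d)$replicateId))
#' buildDetectionMatrix(m, d)
#' @export
buildDetectionMatrix <- function(counts, design, minReads = 10) {
    stopifnot(is(design, "ReplicateDesign"))
    if (is.null(colnames(counts)))
        stop("'counts' needs replicate ids as column names", call. = FALSE)
    minReads <- assertCount(minReads, "minReads", positive = TRUE)
    us <- usableReplicates(design)
    unknown <- setdiff(colnames(counts), us$replicateId)
    if (length(unknown))
        stop("unknown or unusable replicate(s) in counts: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    detected <- (counts >= minReads) * 1L
    storage.mode(detected) <- "integer"
    DetectionMatrix(detected, design, minReads = minReads,
                    counts = counts)
}

#' Construct a detection matrix directly from a binary matrix
#'
#' @param detected Binary (0/1) matrix, OTUs x replicates, replicate ids
#'   as column names.
#' @param design A [ReplicateDesign-class] covering the columns.
#' @param minReads Threshold recorded in the metadata (NA when the matrix
#'   was not derived from counts).
#' @param counts Optional count matrix with identical dimensions.
#' @return A [DetectionMatrix-class].
#' @export
DetectionMatrix <- function(detected, design, minReads = NA_integer_,
                            counts = NULL) {
    stopifnot(is(design, "ReplicateDesign"))
    us <- usableReplicates(design)
    if (is.null(colnames(detected)))
        stop("'detected' needs replicate ids as column names",
             call. = FALSE)
    unknown <- setdiff(colnames(detected), us$replicateId)
    if (length(unknown))
        stop("unknown or unusable replicate(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    storage.mode(detected) <- "integer"
    assays <- list(detected = detected)
    if (!is.null(counts)) assays$counts <- counts
    batch <- us$batchId[match(colnames(detected), us$replicateId)]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(batchId = batch,
                                       row.names = colnames(detected)))
    out <- new("DetectionMatrix", se)
    metadata(out)$minReads <- minReads
    metadata(out)$design <- design
    out
}

#' OTUs detected in at least one replicate
#'
#' @param x A [DetectionMatrix-class].
#' @return Character vector of OTU ids.
#' @export
detectedOTUs <- function(x) {
    stopifnot(is(x, "DetectionMatrix"))
    d <- SummarizedExperiment::assay(x, "detected")
    rownames(d)[rowSums(d) > 0]
}
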