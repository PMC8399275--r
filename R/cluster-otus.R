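#' Dereplicate sequences
#'
#' Exact-string grouping: identical sequences collapse into one record
#' with its member count as abundance. Output is sorted by decreasing
#' abundance, ties broken by ascending lexicographic sequence order, so
#' the result is deterministic regardless of input order.
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector.
#' @return [Biostrings::DNAStringSet] of unique sequences, named
#'   `uniq<i>;size=<abundance>`, with an `abundance` column in `mcols()`.
#' @examples
#' dereplicate(c("AAA", "AAA", "CCC"))
#' @export
dereplicate <- function(seqs) {
    s <- as.character(seqs)
    if (length(s) == 0L) {
        out <- Biostrings::DNAStringSet()
        mcols(out) <- S4Vectors::DataFrame(abundance = integer(0))
        return(out)
    }
    tab <- table(s)
    ord <- order(-as.integer(tab), names(tab), method = "radix")
    uniq <- names(tab)[ord]
    ab <- as.integer(tab)[ord]
    out <- Biostrings::DNAStringSet(uniq)
    names(out) <- sprintf("uniq%d;size=%d", seq_along(uniq), ab)
    mcols(out) <- S4Vectors::DataFrame(abundance = ab)
    out
}

#' Pairwise global-alignment identity
#'
#' Identity is matches / alignment columns of an end-to-end
#' (Needleman-Wunsch) alignment under unit scoring (match +1,
#' mismatch -1, gap -1); alignment columns include gap positions.
#'
#' @param query A single sequence (character or
#'   [Biostrings::DNAString]).
#' @param subjects [Biostrings::DNAStringSet] (or character vector) of
#'   sequences to compare against.
#' @return Numeric identity in `[0, 1]` per subject.
#' @export
alignmentIdentity <- function(query, subjects) {
    subjects <- Biostrings::DNAStringSet(as.character(subjects))
    q <- as.character(query)
    idn <- numeric(length(subjects))
    same <- as.character(subjects) == q
    idn[same] <- 1
    todo <- which(!same)
    if (length(todo)) {
        sm <- Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1)
        aln <- Biostrings::pairwiseAlignment(
            subjects[todo], Biostrings::DNAString(q), type = "global",
            substitutionMatrix = sm, gapOpening = 0, gapExtension = 1)
        cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
        idn[todo] <- Biostrings::nmatch(aln) / cols
    }
    idn
}

#' Greedy abundance-ordered centroid OTU clustering
#'
#' UPARSE-style greedy clustering of dereplicated sequences: scanning in
#' decreasing-abundance order, a sequence joins the existing centroid of
#' highest global-alignment identity when that identity is at least
#' `identityThreshold` (ties go to the earlier centroid); otherwise it
#' founds a new centroid if its abundance is at least `minsize`, and is
#' discarded if not. Input must already be sorted by decreasing abundance
#' (as produced by [dereplicate()]); unsorted input is an error, because
#' the greedy order is part of the algorithm's definition.
#'
#' @param uniques Dereplicated sequences with an `abundance` column in
#'   `mcols()` (see [dereplicate()]).
#' @param identityThreshold Identity radius, in `(0, 1]`; 0.97 is the
#'   canonical OTU radius.
#' @param minsize Minimum abundance for founding a centroid (default 2,
#'   i.e. singletons never seed an OTU).
#' @return List with `centroids` ([Biostrings::DNAStringSet] named
#'   `OTU<i>`, with `size` = summed member abundance in `mcols()`) and
#'   `membership` (data.frame: sequence, abundance, otu; `NA` otu =
#'   discarded singleton-like input).
#' @examples
#' u <- dereplicate(c(rep("ACGTACGTGG", 3), rep("ACGTACGTGA", 2)))
#' clusterOTUs(u, identityThreshold = 0.9)
#' @export
clusterOTUs <- function(uniques, identityThreshold = 0.97, minsize = 2) {
    ab <- mcols(uniques)$abundance
    if (is.null(ab))
        stop("'uniques' must carry an 'abundance' mcols column ",
             "(see dereplicate())", call. = FALSE)
    if (is.unsorted(rev(ab)))
        stop("'uniques' must be sorted by decreasing abundance",
             call. = FALSE)
    if (identityThreshold <= 0 || identityThreshold > 1)
        stop("'identityThreshold' must be in (0, 1]", call. = FALSE)
    minsize <- assertCount(minsize, "minsize", positive = TRUE)
    seqs <- as.character(uniques)
    centroid <- character(0)
    size <- integer(0)
    otu <- rep(NA_character_, length(seqs))
    for (i in seq_along(seqs)) {
        if (length(centroid)) {
            idn <- alignmentIdentity(seqs[i], centroid)
            best <- which.max(idn)  # first centroid wins ties
            if (idn[best] >= identityThreshold) {
                otu[i] <- sprintf("OTU%d", best)
                size[best] <- size[best] + ab[i]
                next
            }
        }
        if (ab[i] >= minsize) {
            centroid <- c(centroid, seqs[i])
            size <- c(size, ab[i])
            otu[i] <- sprintf("OTU%d", length(centroid))
        }
    }
    cents <- Biostrings::DNAStringSet(centroid)
    if (length(centroid)) {
        names(cents) <- sprintf("OTU%d", seq_along(centroid))
        mcols(cents) <- S4Vectors::DataFrame(size = size)
    }
    list(centroids = cents,
         membership = data.frame(sequence = seqs, abundance = ab,
                                 otu = otu, stringsAsFactors = FALSE))
}

#' Map reads to OTU centroids
#'
#' Each read is assigned to the centroid of highest global-alignment
#' identity, provided that identity reaches `identityThreshold`; ties go
#' to the earlier centroid and reads below threshold to every centroid
#' stay unassigned. Reads are dereplicated internally, so identical reads
#' are aligned once. Mapped counts plus unassigned reads always equal the
#' input read count.
#'
#' @param seqs Reads to map ([Biostrings::DNAStringSet] or character).
#' @param centroids Centroid sequences, named (e.g. from [clusterOTUs()]).
#' @param identityThreshold Minimum identity for assignment.
#' @return List with `counts` (named integer per centroid),
#'   `assignments` (per input read: centroid name or NA) and
#'   `nUnassigned`.
#' @export
mapReads <- function(seqs, centroids, identityThreshold = 0.97) {
    if (length(centroids) == 0L)
        stop("'centroids' must be non-empty", call. = FALSE)
    cnames <- names(centroids)
    if (is.null(cnames))
        cnames <- sprintf("OTU%d", seq_along(centroids))
    reads <- as.character(seqs)
    counts <- structure(integer(length(centroids)), names = cnames)
    if (length(reads) == 0L)
        return(list(counts = counts,
                    assignments = character(0), nUnassigned = 0L))
    uniq <- unique(reads)
    assignUniq <- vapply(uniq, function(s) {
        idn <- alignmentIdentity(s, centroids)
        best <- which.max(idn)
        if (idn[best] >= identityThreshold) cnames[best]
        else NA_character_
    }, character(1))
    assignments <- unname(assignUniq[match(reads, uniq)])
    tab <- table(factor(assignments, levels = cnames))
    counts[] <- as.integer(tab)
    list(counts = counts, assignments = assignments,
         nUnassigned = sum(is.na(assignments)))
}
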