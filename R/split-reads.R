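#' Split fused reads into target and 16S fragments
#'
#' Locates the three anchors of the fused layout
#' `[forward][target][bridge][16S][reverse]` by substitution-only
#' (Hamming) sliding-window matching with at most
#' `maxMismatches(primers)` mismatches per anchor; among qualifying
#' windows the leftmost best-scoring hit wins, and each anchor is searched
#' downstream of the previous one. The target fragment is the span
#' between the forward primer and the bridge, the 16S fragment the span
#' between the bridge and the reverse primer. A read in which any anchor
#' is missing (e.g. an unfused target-only amplicon lacking the bridge)
#' is rejected; rejection is a return state, not an error.
#'
#' @param seqs [Biostrings::DNAStringSet] of merged fused reads.
#' @param primers A [PrimerConfig-class].
#' @return List with `target` and `ssu` ([Biostrings::DNAStringSet] of
#'   accepted reads, names preserved) and `status` per input read, one of
#'   `"ok"`, `"no_forward"`, `"no_bridge"`, `"no_reverse"`.
#' @examples
#' pc <- defaultPrimerConfig()
#' read <- Biostrings::DNAStringSet(paste0(
#'     pc@forward, "ACGTACGT", pc@bridge, "TTGGCCAA", pc@reverse))
#' splitFusedReads(read, pc)
#' @export
splitFusedReads <- function(seqs, primers) {
    stopifnot(is(primers, "PrimerConfig"))
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    maxMM <- primers@maxMismatches
    fwd <- Biostrings::DNAString(primers@forward)
    brg <- Biostrings::DNAString(primers@bridge)
    rev <- Biostrings::DNAString(primers@reverse)
    n <- length(seqs)
    # splitting is deterministic per sequence: compute once per unique read
    chars <- as.character(seqs)
    uniq <- unique(chars)
    uStatus <- character(length(uniq))
    uTarget <- character(length(uniq))
    uSsu <- character(length(uniq))
    for (i in seq_along(uniq)) {
        s <- Biostrings::DNAString(uniq[i])
        hF <- .locateAnchor(fwd, s, maxMM, from = 1L)
        if (is.na(hF)) { uStatus[i] <- "no_forward"; next }
        hB <- .locateAnchor(brg, s, maxMM, from = hF + length(fwd))
        if (is.na(hB)) { uStatus[i] <- "no_bridge"; next }
        hR <- .locateAnchor(rev, s, maxMM, from = hB + length(brg))
        if (is.na(hR)) { uStatus[i] <- "no_reverse"; next }
        uStatus[i] <- "ok"
        uTarget[i] <- as.character(Biostrings::subseq(
            s, hF + length(fwd), hB - 1L))
        uSsu[i] <- as.character(Biostrings::subseq(
            s, hB + length(brg), hR - 1L))
    }
    ix <- match(chars, uniq)
    status <- uStatus[ix]
    target <- uTarget[ix]
    ssu <- uSsu[ix]
    ok <- status == "ok"
    tg <- Biostrings::DNAStringSet(target[ok])
    sx <- Biostrings::DNAStringSet(ssu[ok])
    names(tg) <- names(sx) <- names(seqs)[ok]
    list(target = tg, ssu = sx, status = status)
}

# Leftmost window with the minimum Hamming distance <= maxMM, searching
# start positions `from` .. length(subject) - length(pattern) + 1.
# Returns the start position or NA.
.locateAnchor <- function(pattern, subject, maxMM, from = 1L) {
    last <- length(subject) - length(pattern) + 1L
    if (from > last) return(NA_integer_)
    starts <- seq.int(from, last)
    mm <- Biostrings::neditStartingAt(pattern, subject,
                                      starting.at = starts,
                                      with.indels = FALSE)
    best <- min(mm)
    if (best > maxMM) return(NA_integer_)
    starts[which.max(mm == best)]
}
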