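#' Merge read pairs by best ungapped overlap
#'
#' Re-implements paired-end joining as a simple best-overlap merger: R2 is
#' reverse-complemented, every overlap length between `minOverlap` and the
#' shorter read length is scored, and the overlap maximising the number of
#' matching bases among those with mismatch fraction at most
#' `maxMismatchFraction` is chosen (ties broken towards the longer
#' overlap). The consensus takes the higher-quality base at disagreements
#' (R1 wins ties or when no qualities are given); merged qualities take
#' the elementwise maximum over the overlap. A pair with no qualifying
#' overlap is rejected, which is a return state rather than an error.
#'
#' @param r1,r2 [Biostrings::DNAStringSet] (or
#'   [Biostrings::QualityScaledDNAStringSet]) of equal length; `r2` is in
#'   raw orientation and is reverse-complemented internally.
#' @param minOverlap Minimum overlap length in bp.
#' @param maxMismatchFraction Maximum mismatch fraction within the overlap.
#' @return List with `sequences` (merged [Biostrings::DNAStringSet],
#'   successful pairs only, names preserved), `merged` (logical per input
#'   pair) and `overlap` (chosen overlap length, NA when rejected).
#' @examples
#' r1 <- Biostrings::DNAStringSet(c(p = "ACGTACGTAC"))
#' r2 <- Biostrings::reverseComplement(
#'     Biostrings::DNAStringSet(c(p = "CGTACGGTTT")))
#' mergePairs(r1, r2, minOverlap = 4)
#' @export
mergePairs <- function(r1, r2, minOverlap = 10,
                       maxMismatchFraction = 0.1) {
    if (length(r1) != length(r2))
        stop("'r1' and 'r2' must have the same length", call. = FALSE)
    minOverlap <- assertCount(minOverlap, "minOverlap", positive = TRUE)
    q1 <- .qualInts(r1)
    q2 <- .qualInts(r2)
    s1 <- as.character(r1)
    s2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(as.character(r2))))
    q2 <- lapply(q2, rev)
    n <- length(s1)
    merged <- character(n)
    ok <- logical(n)
    ov <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        res <- .mergeOne(s1[i], s2[i], q1[[i]], q2[[i]], minOverlap,
                         maxMismatchFraction)
        if (!is.null(res)) {
            merged[i] <- res$seq
            ov[i] <- res$overlap
            ok[i] <- TRUE
        }
    }
    out <- Biostrings::DNAStringSet(merged[ok])
    names(out) <- names(r1)[ok]
    list(sequences = out, merged = ok, overlap = ov)
}

.qualInts <- function(x) {
    if (is(x, "QualityScaledDNAStringSet")) {
        lapply(as.character(Biostrings::quality(x)), function(q)
            as.integer(charToRaw(q)) - 33L)
    } else {
        lapply(Biostrings::width(x), function(w) rep(30L, w))
    }
}

.mergeOne <- function(s1, s2, q1, q2, minOverlap, maxMismatchFraction) {
    a <- charToRaw(s1)
    b <- charToRaw(s2)
    n1 <- length(a)
    n2 <- length(b)
    best <- NULL
    bestMatches <- -1L
    for (o in seq.int(minOverlap, min(n1, n2))) {
        mism <- sum(a[(n1 - o + 1):n1] != b[1:o])
        if (mism / o > maxMismatchFraction) next
        matches <- o - mism
        if (matches >= bestMatches) {  # ties -> longer overlap
            bestMatches <- matches
            best <- o
        }
    }
    if (is.null(best)) return(NULL)
    o <- best
    i1 <- (n1 - o + 1):n1
    i2 <- 1:o
    cons <- a[i1]
    useB <- (a[i1] != b[i2]) & (q2[i2] > q1[i1])
    cons[useB] <- b[i2][useB]
    list(seq = rawToChar(c(a[seq_len(n1 - o)], cons,
                           b[seq.int(o + 1, length.out = n2 - o)])),
         overlap = o)
}

#' Remove short sequences
#'
#' Keeps sequences of length at least `minLength`, preserving order. The
#' fused-amplicon pipeline removes merged reads shorter than 250 bp (330
#' bp in the companion 16S-only pipeline).
#'
#' @param seqs A [Biostrings::DNAStringSet] (or character vector).
#' @param minLength Minimum length in bp, `>= 1`.
#' @return The surviving subset, same class as the input.
#' @examples
#' lengthFilter(Biostrings::DNAStringSet(c("ACGT", "AC")), 3)
#' @export
lengthFilter <- function(seqs, minLength = 250) {
    minLength <- assertCount(minLength, "minLength", positive = TRUE)
    w <- if (is.character(seqs)) nchar(seqs) else Biostrings::width(seqs)
    seqs[w >= minLength]
}
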