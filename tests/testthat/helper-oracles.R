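# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Needleman-Wunsch global alignment with unit scoring (match +1,
# mismatch -1, gap -1); returns matches / alignment columns via a full DP
# matrix and traceback (diagonal preferred on ties).
oracleAlignmentIdentity <- function(a, b) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A)
    m <- length(B)
    S <- matrix(0, n + 1, m + 1)
    S[, 1] <- 0:-n
    S[1, ] <- 0:-m
    for (i in seq_len(n))
        for (j in seq_len(m))
            S[i + 1, j + 1] <- max(
                S[i, j] + if (A[i] == B[j]) 1 else -1,
                S[i, j + 1] - 1, S[i + 1, j] - 1)
    i <- n; j <- m
    matches <- 0L
    cols <- 0L
    while (i > 0 || j > 0) {
        cols <- cols + 1L
        if (i > 0 && j > 0 &&
            S[i + 1, j + 1] ==
            S[i, j] + (if (A[i] == B[j]) 1 else -1)) {
            if (A[i] == B[j]) matches <- matches + 1L
            i <- i - 1L; j <- j - 1L
        } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
            i <- i - 1L
        } else {
            j <- j - 1L
        }
    }
    matches / cols
}

# Brute-force sliding-window Hamming search: all start positions, all
# mismatch counts, as a plain character-vector scan.
oracleHammingSearch <- function(pattern, subject) {
    p <- strsplit(pattern, "")[[1]]
    s <- strsplit(subject, "")[[1]]
    n <- length(s) - length(p) + 1
    if (n < 1) return(integer(0))
    vapply(seq_len(n), function(i)
        sum(s[i:(i + length(p) - 1)] != p), integer(1))
}

# Brute-force overlap merger: scores every overlap length by direct
# character comparison and returns the merged string per the documented
# rule (max matches, ties to longer overlap), or NULL.
oracleMerge <- function(s1, s2rc, minOverlap, maxMismatchFraction) {
    a <- strsplit(s1, "")[[1]]
    b <- strsplit(s2rc, "")[[1]]
    best <- NULL
    bestMatches <- -1
    for (o in minOverlap:min(length(a), length(b))) {
        mism <- sum(a[(length(a) - o + 1):length(a)] != b[1:o])
        if (mism / o > maxMismatchFraction) next
        if (o - mism >= bestMatches) {
            bestMatches <- o - mism
            best <- o
        }
    }
    if (is.null(best)) return(NULL)
    # equal qualities: r1's base wins overlap disagreements
    paste(c(a, b[seq.int(best + 1, length.out = length(b) - best)]),
          collapse = "")
}

# Exhaustive combination enumeration and per-OTU probabilities computed
# by direct subset/product expansion on the design table.
oracleCombinations <- function(designTb, mode, n) {
    us <- designTb[designTb$usable, , drop = FALSE]
    reps <- split(us$replicateId, factor(us$batchId,
                                         levels = unique(us$batchId)))
    out <- list()
    if (mode == "technical") {
        for (r in reps)
            if (length(r) >= n)
                out <- c(out, utils::combn(r, n, simplify = FALSE))
    } else {
        if (length(reps) >= n)
            for (bs in utils::combn(seq_along(reps), n,
                                    simplify = FALSE)) {
                g <- do.call(expand.grid,
                             c(reps[bs], stringsAsFactors = FALSE))
                out <- c(out, lapply(seq_len(nrow(g)), function(i)
                    as.character(unlist(g[i, ]))))
            }
    }
    out
}

oracleProbabilities <- function(D, designTb, mode, k, n) {
    combos <- oracleCombinations(designTb, mode, n)
    if (length(combos) == 0)
        return(structure(rep(0, nrow(D)), names = rownames(D)))
    hits <- sapply(rownames(D), function(otu)
        sum(vapply(combos, function(cb)
            sum(D[otu, cb]) >= k, logical(1))))
    hits / length(combos)
}

# Two-sided exact binomial p-value by direct tail summation.
oracleBinomP <- function(b, c) {
    n <- b + c
    if (n == 0) return(1)
    pmfs <- vapply(0:n, function(x) choose(n, x) * 0.5^n, numeric(1))
    min(1, 2 * sum(pmfs[seq_len(min(b, c) + 1)]))
}

# Random binary detection matrix on a design, fixed fill rate.
randomDetectionMatrix <- function(designTb, nOTUs, p = 0.4) {
    us <- designTb[designTb$usable, , drop = FALSE]
    matrix(stats::rbinom(nOTUs * nrow(us), 1, p), nOTUs,
           dimnames = list(sprintf("OTU%02d", seq_len(nOTUs)),
                           us$replicateId))
}
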