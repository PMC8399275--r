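#' Validate OTUs under a k-out-of-n replicate strategy
#'
#' Enumerates the strategy's replicate combinations on the design (see
#' [enumerateCombinations()]); an OTU validates a combination when
#' detected in at least `k` of its `n` members. The per-OTU detection
#' probability is the fraction of combinations the OTU validates, and the
#' validated set contains every OTU with probability > 0 (validated in at
#' least one combination). Technical combinations from all batches share
#' one denominator; per-batch probabilities are additionally reported for
#' technical strategies.
#'
#' @param dm A [DetectionMatrix-class].
#' @param strategy A [Strategy-class] or compact string such as
#'   `"biological:2/3"`.
#' @param design Optional [ReplicateDesign-class]; defaults to the design
#'   stored in the matrix metadata.
#' @return A [StrategyResult-class].
#' @examples
#' d <- referenceDesign()
#' m <- matrix(0L, 1, 7,
#'             dimnames = list("OTU1", usableReplicates(d)$replicateId))
#' m[, c("A1", "B1", "C1")] <- 1L
#' validateStrategy(DetectionMatrix(m, d), "biological:3/3")
#' @export
validateStrategy <- function(dm, strategy, design = NULL) {
    stopifnot(is(dm, "DetectionMatrix"))
    if (is.character(strategy)) strategy <- parseStrategy(strategy)
    if (is.null(design)) design <- metadata(dm)$design
    stopifnot(is(design, "ReplicateDesign"))
    D <- SummarizedExperiment::assay(dm, "detected")
    if (!all(colnames(D) %in% usableReplicates(design)$replicateId))
        stop("matrix replicates must be usable replicates of the design",
             call. = FALSE)
    # usable replicates absent from the matrix count as all-undetected, so
    # combination denominators always follow the design
    missing <- setdiff(usableReplicates(design)$replicateId, colnames(D))
    if (length(missing)) {
        pad <- matrix(0L, nrow(D), length(missing),
                      dimnames = list(rownames(D), missing))
        D <- cbind(D, pad)
    }
    combos <- suppressWarnings(
        enumerateCombinations(design, strategy@mode, strategy@n))
    probs <- structure(numeric(nrow(D)), names = rownames(D))
    perBatch <- list()
    if (length(combos)) {
        hits <- vapply(combos, function(cb)
            rowSums(D[, cb, drop = FALSE]) >= strategy@k,
            logical(nrow(D)))
        hits <- matrix(hits, nrow = nrow(D))
        probs[] <- rowMeans(hits)
        if (strategy@mode == "technical") {
            us <- usableReplicates(design)
            batchMap <- structure(us$batchId, names = us$replicateId)
            batchOf <- vapply(combos, function(cb)
                batchMap[[cb[1]]], character(1))
            perBatch <- lapply(split(seq_along(combos), batchOf),
                               function(ix)
                structure(rowMeans(hits[, ix, drop = FALSE]),
                          names = rownames(D)))
        }
    }
    new("StrategyResult", strategy = strategy,
        nCombinations = length(combos), probabilities = probs,
        validated = names(probs)[probs > 0], perBatch = perBatch)
}

#' Detection-efficiency table of a strategy result
#'
#' OTUs sorted by decreasing detection probability (ties by OTU id), with
#' the cumulative probability sum — the strategy's cumulative efficiency
#' at detecting target-carrying hosts.
#'
#' @param result A [StrategyResult-class].
#' @param dropZero Drop OTUs with probability 0 (default keeps them).
#' @return data.frame with columns `otu`, `probability`, `cumulative`;
#'   the summed probability is in `attr(x, "total")`.
#' @export
detectionEfficiency <- function(result, dropZero = FALSE) {
    stopifnot(is(result, "StrategyResult"))
    p <- detectionProbabilities(result)
    if (dropZero) p <- p[p > 0]
    if (length(p) == 0L) {
        out <- data.frame(otu = character(0), probability = numeric(0),
                          cumulative = numeric(0),
                          stringsAsFactors = FALSE)
        attr(out, "total") <- 0
        return(out)
    }
    ord <- order(-p, names(p), method = "radix")
    out <- data.frame(otu = names(p)[ord], probability = unname(p[ord]),
                      cumulative = cumsum(unname(p[ord])),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- sum(p)
    out
}

#' McNemar's test for paired OTU validation outcomes
#'
#' Tests whether two validation strategies disagree symmetrically across
#' OTUs, from the discordant counts `b` (validated under A only) and `c`
#' (validated under B only). When `b + c < 25` the exact two-sided
#' binomial p-value \eqn{\min(1, 2 P(X \le \min(b,c)))} with
#' \eqn{X \sim Bin(b+c, 1/2)} is used; otherwise the continuity-corrected
#' chi-square statistic \eqn{(|b-c|-1)^2/(b+c)} on 1 df. With no
#' discordant pairs the p-value is 1.
#'
#' @param x,y Logical vectors of per-OTU validation under the two
#'   strategies (same length), or the discordant counts `b` and `c`
#'   directly when `counts = TRUE`.
#' @param counts Interpret `x`, `y` as the counts `b`, `c`.
#' @return Object of class `"htest"` with `statistic` (chi-square, NA for
#'   the exact variant), `parameter` (b, c), `p.value` and `method`.
#' @examples
#' mcnemarTest(10, 0, counts = TRUE)$p.value # 0.001953125
#' @export
mcnemarTest <- function(x, y, counts = FALSE) {
    if (counts) {
        b <- assertCount(x, "b")
        c <- assertCount(y, "c")
    } else {
        if (length(x) != length(y) || length(x) < 1L)
            stop("'x' and 'y' must be logical vectors of equal positive ",
                 "length", call. = FALSE)
        b <- sum(x & !y)
        c <- sum(!x & y)
    }
    nd <- b + c
    if (nd == 0L) {
        p <- 1
        stat <- NA_real_
        method <- "McNemar test (no discordant pairs)"
    } else if (nd < 25L) {
        p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
        stat <- NA_real_
        method <- "Exact McNemar test (two-sided binomial)"
    } else {
        stat <- (abs(b - c) - 1)^2 / nd
        p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
        method <- "McNemar chi-squared test with continuity correction"
    }
    structure(list(statistic = c("chi-squared" = stat),
                   parameter = c(b = b, c = c),
                   p.value = p, method = method,
                   data.name = "paired validation outcomes"),
              class = "htest")
}

#' Cross-tabulate and test two validation strategies
#'
#' Applies both strategies to the same detection matrix, cross-tabulates
#' validated-set membership over all OTUs detected in at least one
#' replicate, and runs [mcnemarTest()] on the paired outcomes. A small
#' p-value indicates asymmetric disagreement — one strategy validates
#' OTUs the other systematically misses, the signature of dependence
#' between technical replicates of a shared bead batch.
#'
#' @param dm A [DetectionMatrix-class].
#' @param strategyA,strategyB [Strategy-class] objects or compact strings.
#' @param design Optional [ReplicateDesign-class] (defaults to the
#'   matrix's).
#' @return List with `table` (2x2 matrix, A by B), `test` (htest),
#'   `validatedA`, `validatedB` and `universe` (the detected OTUs used).
#' @export
compareStrategies <- function(dm, strategyA, strategyB, design = NULL) {
    uni <- detectedOTUs(dm)
    rA <- validateStrategy(dm, strategyA, design)
    rB <- validateStrategy(dm, strategyB, design)
    inA <- uni %in% validatedOTUs(rA)
    inB <- uni %in% validatedOTUs(rB)
    tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                    sum(!inA & inB), sum(!inA & !inB)), 2, 2,
                  dimnames = list(A = c("validated", "not"),
                                  B = c("validated", "not")))
    list(table = tab,
         test = if (length(uni)) mcnemarTest(inA, inB) else
             mcnemarTest(0, 0, counts = TRUE),
         validatedA = validatedOTUs(rA), validatedB = validatedOTUs(rB),
         universe = uni)
}

#' Assign ordinal confidence levels to detected OTUs
#'
#' Each detected OTU receives the highest confidence level whose defining
#' strategy validates it, following the ranking
#' LC5 (`3/3 biological`) > LC4 (`2/2` or `2/3 biological`) >
#' LC3 (`3/3 technical`) > LC2 (`2/2` or `2/3 technical`) >
#' LC1 (detected in a single replicate only, not validated with an
#' acceptable risk). Strategies the design cannot supply (e.g. biological
#' triplicates with fewer than three usable batches) are skipped.
#'
#' @param dm A [DetectionMatrix-class].
#' @param design Optional [ReplicateDesign-class].
#' @return data.frame with columns `otu` and `level` (integer 1-5), one
#'   row per detected OTU, ordered by decreasing level then OTU id.
#' @examples
#' d <- referenceDesign()
#' m <- matrix(0L, 1, 7,
#'             dimnames = list("OTU1", usableReplicates(d)$replicateId))
#' m[, c("A1", "B1", "C1")] <- 1L
#' assignConfidenceLevels(DetectionMatrix(m, d)) # LC5
#' @export
assignConfidenceLevels <- function(dm, design = NULL) {
    stopifnot(is(dm, "DetectionMatrix"))
    if (is.null(design)) design <- metadata(dm)$design
    detected <- detectedOTUs(dm)
    if (length(detected) == 0L)
        return(data.frame(otu = character(0), level = integer(0),
                          stringsAsFactors = FALSE))
    levelStrategies <- list(
        `5` = list(Strategy("biological", 3, 3)),
        `4` = list(Strategy("biological", 2, 2),
                   Strategy("biological", 2, 3)),
        `3` = list(Strategy("technical", 3, 3)),
        `2` = list(Strategy("technical", 2, 2),
                   Strategy("technical", 2, 3)))
    level <- structure(rep(1L, length(detected)), names = detected)
    for (lv in names(levelStrategies)) {
        validated <- unique(unlist(lapply(levelStrategies[[lv]],
            function(s) validatedOTUs(validateStrategy(dm, s, design)))))
        hit <- detected %in% validated & level < as.integer(lv)
        level[hit] <- as.integer(lv)
    }
    out <- data.frame(otu = detected, level = unname(level),
                      stringsAsFactors = FALSE)
    out[order(-out$level, out$otu), , drop = FALSE]
}

#' Validated-set overlap across strategies
#'
#' Per-OTU membership of the validated set of each strategy, plus counts
#' of every region of the resulting set algebra (the tabular equivalent
#' of a Venn diagram of validated OTUs).
#'
#' @param dm A [DetectionMatrix-class].
#' @param strategies List of two or more [Strategy-class] objects or
#'   compact strings; names become column labels.
#' @param design Optional [ReplicateDesign-class].
#' @return List with `membership` (logical matrix, detected OTUs x
#'   strategies) and `regions` (data.frame: one row per membership
#'   pattern with its OTU count).
#' @export
strategyOverlap <- function(dm, strategies, design = NULL) {
    if (length(strategies) < 2L)
        stop("need at least two strategies", call. = FALSE)
    strategies <- lapply(strategies, function(s)
        if (is.character(s)) parseStrategy(s) else s)
    labels <- names(strategies)
    if (is.null(labels) || any(labels == ""))
        labels <- vapply(strategies, strategyLabel, character(1))
    uni <- detectedOTUs(dm)
    membership <- vapply(strategies, function(s)
        uni %in% validatedOTUs(validateStrategy(dm, s, design)),
        logical(length(uni)))
    membership <- matrix(membership, nrow = length(uni),
                         dimnames = list(uni, labels))
    pattern <- apply(membership, 1, function(r)
        paste(as.integer(r), collapse = ""))
    regions <- as.data.frame(table(pattern = pattern),
                             stringsAsFactors = FALSE)
    names(regions)[2] <- "count"
    list(membership = membership, regions = regions)
}
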