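#' Construct a replicate design
#'
#' @param batchId,replicateId,usable Parallel vectors, one entry per
#'   technical replicate; or pass a data.frame with those columns as the
#'   first argument.
#' @return A [ReplicateDesign-class].
#' @examples
#' ReplicateDesign(batchId = rep(c("A", "B"), each = 3),
#'                 replicateId = c("A1", "A2", "A3", "B1", "B2", "B3"))
#' @export
ReplicateDesign <- function(batchId, replicateId, usable = TRUE) {
    if (is.data.frame(batchId)) {
        tb <- batchId
        if (!all(c("batchId", "replicateId") %in% names(tb)))
            stop("design data.frame needs batchId and replicateId columns",
                 call. = FALSE)
        if (is.null(tb$usable)) tb$usable <- TRUE
    } else {
        tb <- data.frame(batchId = as.character(batchId),
                         replicateId = as.character(replicateId),
                         usable = rep_len(as.logical(usable),
                                          length(replicateId)),
                         stringsAsFactors = FALSE)
    }
    new("ReplicateDesign", table = tb)
}

#' The reference epicPCR replicate design
#'
#' Three bead batches with three technical replicates each; sequencing of
#' two replicates of the third batch failed quality requirements, leaving
#' usable replicate counts (3, 3, 1). This design admits 15 biological
#' duplicate combinations and 9 biological triplicate combinations.
#'
#' @return A [ReplicateDesign-class].
#' @examples
#' referenceDesign()
#' @export
referenceDesign <- function() {
    ReplicateDesign(
        batchId = rep(c("A", "B", "C"), each = 3),
        replicateId = c("A1", "A2", "A3", "B1", "B2", "B3",
                        "C1", "C2", "C3"),
        usable = c(rep(TRUE, 7), FALSE, FALSE))
}

#' Construct a k-out-of-n validation strategy
#'
#' @param mode `"technical"` (combinations drawn within one batch) or
#'   `"biological"` (one replicate from each of `n` distinct batches).
#' @param k Minimum detections within a combination, `1 <= k <= n`.
#' @param n Combination size.
#' @return A [Strategy-class].
#' @examples
#' Strategy("biological", k = 3, n = 3)
#' parseStrategy("technical:2/3")
#' @export
Strategy <- function(mode, k, n) {
    new("Strategy", mode = match.arg(mode, c("technical", "biological")),
        k = assertCount(k, "k", positive = TRUE),
        n = assertCount(n, "n", positive = TRUE))
}

#' @rdname Strategy
#' @param spec Compact form `"mode:k/n"`, e.g. `"biological:2/3"`.
#' @export
parseStrategy <- function(spec) {
    m <- regmatches(spec,
        regexec("^(technical|biological):([0-9]+)/([0-9]+)$", spec))[[1]]
    if (length(m) != 4)
        stop("cannot parse strategy '", spec,
             "' (expected e.g. 'technical:2/3')", call. = FALSE)
    Strategy(m[2], as.integer(m[3]), as.integer(m[4]))
}

strategyLabel <- function(strategy)
    sprintf("%s:%d/%d", strategy@mode, strategy@k, strategy@n)

#' Enumerate replicate combinations for a validation strategy
#'
#' Technical mode returns every size-`n` subset of usable replicates
#' within each batch, pooled over batches; biological mode returns every
#' cross-product taking one usable replicate from each of `n` distinct
#' batches. Ordering is deterministic: batches in design order, replicates
#' in design order, and (biological mode) the first batch's replicate
#' varying fastest. With the reference (3, 3, 1) design this gives
#' 15 biological duplicates, 9 biological triplicates, 6 technical
#' duplicates and 2 technical triplicates.
#'
#' @param design A [ReplicateDesign-class].
#' @param mode `"technical"` or `"biological"`.
#' @param n Combination size, `>= 2`.
#' @return List of character vectors of replicate ids; empty (with a
#'   warning) when the design cannot supply any combination of size `n`.
#' @examples
#' length(enumerateCombinations(referenceDesign(), "biological", 2)) # 15
#' @export
enumerateCombinations <- function(design,
                                  mode = c("technical", "biological"),
                                  n) {
    stopifnot(is(design, "ReplicateDesign"))
    mode <- match.arg(mode)
    n <- assertCount(n, "n", positive = TRUE)
    if (n < 2L) stop("'n' must be >= 2", call. = FALSE)
    us <- usableReplicates(design)
    byBatch <- split(us$replicateId, factor(us$batchId,
                                            levels = unique(us$batchId)))
    combos <- list()
    if (mode == "technical") {
        for (reps in byBatch) {
            if (length(reps) >= n)
                combos <- c(combos, asplit(
                    t(utils::combn(reps, n)), 1))
        }
    } else {
        if (length(byBatch) >= n) {
            batchSets <- utils::combn(names(byBatch), n, simplify = FALSE)
            for (bs in batchSets) {
                grid <- expand.grid(byBatch[bs], stringsAsFactors = FALSE,
                                    KEEP.OUT.ATTRS = FALSE)
                combos <- c(combos,
                            lapply(seq_len(nrow(grid)), function(i)
                                unname(unlist(grid[i, ]))))
            }
        }
    }
    combos <- lapply(combos, as.character)
    if (length(combos) == 0L)
        warning("design provides no ", mode, " combination of size ", n,
                call. = FALSE)
    combos
}
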