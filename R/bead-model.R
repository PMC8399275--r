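#' Construct a Poisson bead-occupancy model
#'
#' @param lambda Mean occupancy (expected cells per bead), `>= 0`.
#' @return An [OccupancyModel-class] object.
#' @examples
#' OccupancyModel(0.1)
#' @export
OccupancyModel <- function(lambda) {
    assertScalarNumeric(lambda, "lambda")
    new("OccupancyModel", lambda = as.numeric(lambda))
}

#' Mean occupancy implied by an observed empty-bead fraction
#'
#' Inverts the Poisson zero class: if a fraction `emptyFraction` of beads
#' carries no cell, the implied mean occupancy is
#' \eqn{\lambda = -\ln(\text{emptyFraction})}.
#'
#' @param emptyFraction Observed fraction of empty beads, in `(0, 1]`.
#' @return Mean occupancy \eqn{\lambda} (vectorised).
#' @examples
#' lambdaFromEmptyFraction(0.9048374) # ~0.1
#' @seealso [occupancyPmf()]
#' @export
lambdaFromEmptyFraction <- function(emptyFraction) {
    if (!is.numeric(emptyFraction) || length(emptyFraction) == 0 ||
        anyNA(emptyFraction) ||
        any(emptyFraction <= 0) || any(emptyFraction > 1))
        stop("'emptyFraction' must be in (0, 1]", call. = FALSE)
    -log(emptyFraction)
}

#' Poisson probability that a bead contains k cells
#'
#' \eqn{P(k;\lambda) = \lambda^k e^{-\lambda} / k!}. At the occupancy used
#' for epicPCR bead batches (\eqn{\lambda = 0.1}, i.e. ~90\% empty beads)
#' the doublet probability is \eqn{P(2;0.1) = 4.5\times 10^{-3}}.
#'
#' @param lambda Mean occupancy, `>= 0`; may be an [OccupancyModel-class].
#' @param k Non-negative integer cell count (vectorised).
#' @return Probability of observing exactly `k` cells in a bead.
#' @examples
#' occupancyPmf(0.1, 2) # 0.0045242...
#' @export
occupancyPmf <- function(lambda, k) {
    if (is(lambda, "OccupancyModel")) lambda <- meanOccupancy(lambda)
    if (!is.numeric(lambda) || anyNA(lambda) || any(lambda < 0))
        stop("'lambda' must be non-negative", call. = FALSE)
    if (!is.numeric(k) || anyNA(k) || any(k < 0) || any(k %% 1 != 0))
        stop("'k' must be a non-negative integer", call. = FALSE)
    stats::dpois(k, lambda)
}

#' Probability of a doublet bead containing one target carrier
#'
#' Probability that a bead holds two cells of which (at least) one carries
#' the target sequence, given the carrier relative frequency `f` in the
#' population. The default follows the field's working formula
#' \eqn{2 f \, P(2;\lambda)}; `exact = TRUE` applies the
#' exactly-one-carrier refinement \eqn{2 f (1-f) P(2;\lambda)}, which
#' differs appreciably only when carriers are common.
#'
#' @param lambda Mean occupancy; may be an [OccupancyModel-class].
#' @param f Carrier relative abundance, in `[0, 1]`.
#' @param exact Use the \eqn{2f(1-f)} refinement instead of \eqn{2f}.
#' @return Probability (vectorised over `f`).
#' @examples
#' targetDoubletProbability(0.1, 1e-3)
#' @export
targetDoubletProbability <- function(lambda, f, exact = FALSE) {
    if (!is.numeric(f) || anyNA(f) || any(f < 0) || any(f > 1))
        stop("'f' must be in [0, 1]", call. = FALSE)
    p2 <- occupancyPmf(lambda, 2L)
    if (exact) 2 * f * (1 - f) * p2 else 2 * f * p2
}

#' Apply the bead-batch quality rules
#'
#' A batch passes when strictly more than `emptyThreshold` (default 90\%)
#' of beads are empty and at least `singletonThreshold` (default 85\%) of
#' the non-empty beads carry a single cell. Under these conditions the
#' probability of a target-carrying doublet is considered negligible and
#' the batch can enter fusion PCR.
#'
#' When no bead is occupied the singleton fraction is undefined; it is
#' reported as 1 with a warning and `degenerate = TRUE`, a conservative
#' pass since there is no evidence of multi-cell beads.
#'
#' @param nEmpty,nSingle,nMulti Counts of beads with 0, 1, >1 cells.
#' @param emptyThreshold Strict lower bound on the empty fraction.
#' @param singletonThreshold Inclusive lower bound on the singleton
#'   fraction of non-empty beads.
#' @return A [BeadQCResult-class].
#' @examples
#' assessBeadBatch(910, 80, 10)
#' @export
assessBeadBatch <- function(nEmpty, nSingle, nMulti,
                            emptyThreshold = 0.90,
                            singletonThreshold = 0.85) {
    nEmpty <- assertCount(nEmpty, "nEmpty")
    nSingle <- assertCount(nSingle, "nSingle")
    nMulti <- assertCount(nMulti, "nMulti")
    total <- nEmpty + nSingle + nMulti
    if (total == 0L)
        stop("all bead counts are zero", call. = FALSE)
    emptyFrac <- nEmpty / total
    nonEmpty <- nSingle + nMulti
    degenerate <- nonEmpty == 0L
    if (degenerate) {
        warning("no occupied beads: singleton fraction undefined, ",
                "reported as 1", call. = FALSE)
        singleFrac <- 1
    } else {
        singleFrac <- nSingle / nonEmpty
    }
    new("BeadQCResult",
        nEmpty = nEmpty, nSingle = nSingle, nMulti = nMulti,
        emptyFraction = emptyFrac, singletonFraction = singleFrac,
        passed = emptyFrac > emptyThreshold &&
            singleFrac >= singletonThreshold,
        degenerate = degenerate,
        emptyThreshold = emptyThreshold,
        singletonThreshold = singletonThreshold)
}

#' Quality-check a table of bead batches
#'
#' Vectorised front end to [assessBeadBatch()] for a per-batch count table,
#' adding the implied mean occupancy and doublet probabilities.
#'
#' @param counts data.frame with columns `batch_id`, `n_empty`, `n_single`,
#'   `n_multi`.
#' @param f Optional carrier frequency for the target-doublet column.
#' @inheritParams assessBeadBatch
#' @return data.frame with fractions, `lambda` (from the empty fraction),
#'   `doublet_probability`, optionally `target_doublet_probability`, and
#'   `passed`.
#' @export
qcBeadBatches <- function(counts, f = NULL, emptyThreshold = 0.90,
                          singletonThreshold = 0.85) {
    need <- c("batch_id", "n_empty", "n_single", "n_multi")
    if (!is.data.frame(counts) || !all(need %in% names(counts)))
        stop("'counts' needs columns ", paste(need, collapse = ", "),
             call. = FALSE)
    res <- lapply(seq_len(nrow(counts)), function(i)
        assessBeadBatch(counts$n_empty[i], counts$n_single[i],
                        counts$n_multi[i], emptyThreshold,
                        singletonThreshold))
    ef <- vapply(res, emptyFraction, numeric(1))
    lam <- ifelse(ef > 0, -log(ef), NA_real_)
    out <- data.frame(
        batch_id = counts$batch_id,
        n_empty = counts$n_empty, n_single = counts$n_single,
        n_multi = counts$n_multi,
        empty_fraction = ef,
        singleton_fraction = vapply(res, singletonFraction, numeric(1)),
        lambda = lam,
        doublet_probability = stats::dpois(2, lam),
        stringsAsFactors = FALSE)
    if (!is.null(f))
        out$target_doublet_probability <- 2 * f * stats::dpois(2, lam)
    out$passed <- vapply(res, qcPassed, logical(1))
    out
}
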