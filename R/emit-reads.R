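#' Construct a primer configuration
#'
#' @param forward,bridge,reverse Anchor sequences as they appear on the
#'   forward strand of the merged fused amplicon
#'   `[forward][target][bridge][16S][reverse]`.
#' @param maxMismatches Mismatch budget per primer when locating anchors.
#' @return A [PrimerConfig-class].
#' @examples
#' defaultPrimerConfig()
#' @export
PrimerConfig <- function(forward, bridge, reverse, maxMismatches = 2) {
    new("PrimerConfig", forward = toupper(forward),
        bridge = toupper(bridge), reverse = toupper(reverse),
        maxMismatches = assertCount(maxMismatches, "maxMismatches"))
}

#' @rdname PrimerConfig
#' @details `defaultPrimerConfig()` supplies fixed synthetic 20-mers used
#'   by the simulator; real experiments must configure their own primer
#'   and bridge sequences.
#' @export
defaultPrimerConfig <- function() {
    PrimerConfig(forward = "TGCAGGACCTTGACGATCAT",
                 bridge  = "CGTACGGAAGGTTCAGATCC",
                 reverse = "ATCGTTGGCACCAGTTCGTA")
}

#' Emit fused amplicon reads from an OTU count table
#'
#' For every (taxon, replicate) cell of `counts`, emits that many reads
#' following the fused layout
#' `[forward][target fragment][bridge][16S fragment][reverse]`, with
#' independent per-base substitution errors. Two contaminant classes can
#' be mixed in: unfused target-only amplicons
#' (`[forward][target][reverse]`, no bridge, rejected by the splitter) and
#' cross-taxon chimeras whose 16S fragment comes from a random other
#' taxon. Every read receives a provenance record; read names carry the
#' replicate and a running index (`read000001;rep=A1`), which is how the
#' processing stage demultiplexes replicates.
#'
#' @param counts Integer matrix, carrier taxa x replicates.
#' @param community The [Community-class] supplying fragments.
#' @param primers A [PrimerConfig-class].
#' @param errorRate Per-base substitution probability.
#' @param chimeraRate,unfusedRate Contaminant read fractions.
#' @param paired Emit paired reads (R1 = first `readLength` bases, R2 =
#'   reverse complement of the last `readLength` bases, constant Q40
#'   qualities) instead of merged sequences.
#' @param readLength Read length in paired mode; pairs must be long
#'   enough to overlap by at least 10 bp on every amplicon.
#' @param seed Integer seed; the same seed reproduces identical reads.
#' @return List with `provenance` (data.frame: read, replicateId, taxon,
#'   ssuTaxon, type) and either `sequences` (merged
#'   [Biostrings::DNAStringSet]) or `r1`/`r2`
#'   ([Biostrings::QualityScaledDNAStringSet]) in paired mode.
#' @export
emitFusedReads <- function(counts, community, primers = defaultPrimerConfig(),
                           errorRate = 0, chimeraRate = 0, unfusedRate = 0,
                           paired = FALSE, readLength = 250, seed = 1) {
    stopifnot(is(community, "Community"), is(primers, "PrimerConfig"))
    if (errorRate < 0 || errorRate >= 1)
        stop("'errorRate' must be in [0, 1)", call. = FALSE)
    if (chimeraRate + unfusedRate > 1)
        stop("contaminant rates must sum to <= 1", call. = FALSE)
    taxa <- rownames(counts)
    if (!all(taxa %in% carrierIds(community)))
        stop("count rows must be carrier taxa of the community",
             call. = FALSE)
    s16 <- as.character(fragments16S(community))
    tg <- as.character(targetFragments(community))
    allTaxa <- taxonTable(community)$id
    idx <- which(counts > 0, arr.ind = TRUE)
    nReads <- sum(counts)
    taxon <- rep(taxa[idx[, 1]], counts[idx])
    repl <- rep(colnames(counts)[idx[, 2]], counts[idx])
    withSeed(deriveSeed(seed, 977L), {
        type <- rep("fused", nReads)
        u <- stats::runif(nReads)
        type[u < chimeraRate] <- "chimera"
        type[u >= chimeraRate & u < chimeraRate + unfusedRate] <- "unfused"
        ssuTaxon <- taxon
        chim <- type == "chimera"
        if (any(chim))
            ssuTaxon[chim] <- vapply(taxon[chim], function(t)
                sample(setdiff(allTaxa, t), 1), character(1))
        ssuTaxon[type == "unfused"] <- NA_character_
        amplicon <- ifelse(
            type == "unfused",
            paste0(primers@forward, tg[taxon], primers@reverse),
            paste0(primers@forward, tg[taxon], primers@bridge,
                   s16[ssuTaxon], primers@reverse))
        name <- sprintf("read%06d;rep=%s", seq_len(nReads), repl)
        prov <- data.frame(read = name, replicateId = repl, taxon = taxon,
                           ssuTaxon = ssuTaxon, type = type,
                           stringsAsFactors = FALSE)
        if (!paired) {
            seqs <- .substitutionErrors(amplicon, errorRate)
            out <- Biostrings::DNAStringSet(seqs)
            names(out) <- name
            return(list(sequences = out, provenance = prov))
        }
        readLength <- assertCount(readLength, "readLength", positive = TRUE)
        len <- nchar(amplicon)
        if (any(2 * readLength - len < 10))
            stop("'readLength' too short: pairs cannot overlap by 10 bp ",
                 "on the longest amplicon (", max(len), " bp)",
                 call. = FALSE)
        r1 <- .substitutionErrors(substr(amplicon, 1, pmin(readLength, len)),
                                  errorRate)
        r2raw <- substr(amplicon, pmax(1, len - readLength + 1), len)
        r2 <- .substitutionErrors(as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(r2raw))), errorRate)
        mk <- function(x) {
            s <- Biostrings::DNAStringSet(x)
            names(s) <- name
            Biostrings::QualityScaledDNAStringSet(
                s, Biostrings::PhredQuality(strrep("I", nchar(x))))
        }
        list(r1 = mk(r1), r2 = mk(r2), provenance = prov)
    })
}

# iid per-base substitutions at rate `rate` on a character vector.
.substitutionErrors <- function(seqs, rate) {
    if (rate == 0 || length(seqs) == 0L) return(seqs)
    bases <- c("A", "C", "G", "T")
    vapply(seqs, function(s) {
        n <- nchar(s)
        hits <- which(stats::runif(n) < rate)
        if (!length(hits)) return(s)
        ch <- strsplit(s, "")[[1]]
        ch[hits] <- vapply(ch[hits], function(b)
            sample(setdiff(bases, b), 1), character(1))
        paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}
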