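#' Process fused amplicon reads into an OTU detection matrix
#'
#' Runs the bespoke processing chain on merged reads (or read pairs):
#' optional pair merging, length filtering (reads shorter than
#' `minLength` are removed), bridge-primer splitting into target and 16S
#' fragments, pooled dereplication of the 16S fragments, greedy centroid
#' OTU clustering, per-replicate read mapping and the minimum-read
#' detection rule. Replicates are demultiplexed from the `;rep=<id>` tag
#' in read names (as written by [emitFusedReads()]).
#'
#' @param seqs Merged reads ([Biostrings::DNAStringSet]) or, with `r2`,
#'   the forward reads of pairs.
#' @param design A [ReplicateDesign-class]; count columns cover all its
#'   usable replicates.
#' @param primers A [PrimerConfig-class].
#' @param r2 Optional reverse reads; triggers pair merging.
#' @param minLength Minimum merged-read length (default 250 bp).
#' @param identityThreshold OTU identity radius (default 0.97).
#' @param minsize Minimum abundance to found a centroid (default 2).
#' @param minReads Detection threshold (default 10; 100 reproduces the
#'   original epicPCR dialect).
#' @param minOverlap,maxMismatchFraction Pair-merging parameters.
#' @return List with `detection` ([DetectionMatrix-class]), `counts`
#'   (OTUs x usable replicates), `centroids`, `membership`, and a `stats`
#'   list (input/merged/filtered/split/mapped read tallies).
#' @export
processAmplicons <- function(seqs, design,
                             primers = defaultPrimerConfig(), r2 = NULL,
                             minLength = 250, identityThreshold = 0.97,
                             minsize = 2, minReads = 10,
                             minOverlap = 10, maxMismatchFraction = 0.1) {
    stopifnot(is(design, "ReplicateDesign"))
    nInput <- length(seqs)
    if (!is.null(r2)) {
        mg <- mergePairs(seqs, r2, minOverlap = minOverlap,
                         maxMismatchFraction = maxMismatchFraction)
        seqs <- mg$sequences
    }
    nMerged <- length(seqs)
    seqs <- lengthFilter(seqs, minLength)
    nKept <- length(seqs)
    sp <- splitFusedReads(seqs, primers)
    repOf <- sub(".*;rep=([^;]+).*", "\\1", names(sp$ssu))
    uniq <- dereplicate(sp$ssu)
    cl <- clusterOTUs(uniq, identityThreshold = identityThreshold,
                      minsize = minsize)
    us <- usableReplicates(design)
    counts <- matrix(0L, length(cl$centroids), nrow(us),
                     dimnames = list(names(cl$centroids),
                                     us$replicateId))
    nUnassigned <- 0L
    if (length(cl$centroids) && length(sp$ssu)) {
        bad <- setdiff(unique(repOf), us$replicateId)
        if (length(bad))
            stop("read replicate tag(s) not usable replicates of the ",
                 "design: ", paste(bad, collapse = ", "), call. = FALSE)
        mp <- mapReads(sp$ssu, cl$centroids, identityThreshold)
        nUnassigned <- mp$nUnassigned
        hit <- !is.na(mp$assignments)
        tab <- table(factor(mp$assignments[hit],
                            levels = names(cl$centroids)),
                     factor(repOf[hit], levels = us$replicateId))
        counts[, ] <- as.integer(tab)
    }
    detection <- buildDetectionMatrix(counts, design, minReads = minReads)
    list(detection = detection, counts = counts,
         centroids = cl$centroids, membership = cl$membership,
         stats = list(nInput = nInput, nMerged = nMerged,
                      nLengthKept = nKept,
                      splitStatus = table(sp$status),
                      nSplit = length(sp$ssu),
                      nMapped = sum(counts), nUnassigned = nUnassigned))
}

#' Build a run configuration
#'
#' Assembles the full parameter set of a simulate-process-validate run.
#' The `dialect` presets reflect the two analysis generations: the
#' original epicPCR dialect uses a 100-read OTU detection threshold and
#' prefers technical-triplicate (3/3) validation; the epicPCR 2.0 dialect
#' uses a 10-read threshold and prefers biological-triplicate (3/3)
#' validation. Partial lists override the corresponding defaults.
#'
#' @param dialect `"2.0"` (default) or `"original"`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param outputDir Output directory for [runPipeline()] artifacts.
#' @param community,beads,replication,emission,processing Stage parameter
#'   lists (see Details in the package vignette); partial lists are
#'   merged over defaults.
#' @param design A [ReplicateDesign-class].
#' @param primers A [PrimerConfig-class].
#' @param strategies Character vector of strategies to report.
#' @return Named list of class `"epicpcrRunConfig"`.
#' @examples
#' cfg <- runConfig(dialect = "original")
#' cfg$processing$minReads # 100
#' @export
runConfig <- function(dialect = c("2.0", "original"), seed = 1,
                      outputDir = tempfile("epicpcr_run"),
                      community = list(), beads = list(),
                      replication = list(), emission = list(),
                      processing = list(),
                      design = referenceDesign(),
                      primers = defaultPrimerConfig(),
                      strategies = c("biological:3/3", "biological:2/3",
                                     "biological:2/2", "technical:3/3",
                                     "technical:2/3", "technical:2/2")) {
    dialect <- match.arg(dialect)
    cfg <- list(
        dialect = dialect, seed = seed, outputDir = outputDir,
        community = utils::modifyList(
            list(nTaxa = 1200, sigma = 1.5, nCarriers = 600, f = 1e-3,
                 fragmentLength16S = 250, fragmentLengthTarget = 120),
            community),
        beads = utils::modifyList(
            list(nBeads = 1e5, lambda = 0.1), beads),
        replication = utils::modifyList(
            list(amplificationSuccess = 0.8, readsPerPositive = 10),
            replication),
        emission = utils::modifyList(
            list(errorRate = 0, chimeraRate = 0, unfusedRate = 0,
                 paired = FALSE, readLength = 250), emission),
        processing = utils::modifyList(
            list(minLength = 250, identityThreshold = 0.97, minsize = 2,
                 minReads = if (dialect == "2.0") 10 else 100),
            processing),
        design = design, primers = primers,
        strategies = strategies,
        preferredStrategy = if (dialect == "2.0") "biological:3/3"
                            else "technical:3/3")
    class(cfg) <- "epicpcrRunConfig"
    cfg
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys mirror the [runConfig()] arguments; `design` may be a
#' mapping with `batch_id`, `replicate_id`, `usable` vectors, and
#' `primers` a mapping with `forward`, `bridge`, `reverse`,
#' `max_mismatches`.
#'
#' @param path YAML file path.
#' @return An `"epicpcrRunConfig"` list.
#' @export
loadRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[intersect(names(y),
                        c("dialect", "seed", "outputDir", "community",
                          "beads", "replication", "emission",
                          "processing", "strategies"))]
    if (!is.null(y$design))
        args$design <- ReplicateDesign(
            batchId = y$design$batch_id,
            replicateId = y$design$replicate_id,
            usable = if (is.null(y$design$usable)) TRUE
                     else as.logical(y$design$usable))
    if (!is.null(y$primers))
        args$primers <- PrimerConfig(
            y$primers$forward, y$primers$bridge, y$primers$reverse,
            maxMismatches = if (is.null(y$primers$max_mismatches)) 2
                            else y$primers$max_mismatches)
    do.call(runConfig, args)
}

#' Run the full simulate-process-validate pipeline
#'
#' Simulates a community, bead batches and fused reads under the
#' configuration, processes the reads into an OTU detection matrix,
#' applies the validation strategies, confidence levels and McNemar
#' strategy comparisons, and writes every artifact plus a manifest (stage
#' parameters, seed, file checksums) and a machine-readable summary to
#' the output directory. The same configuration and seed always produce
#' byte-identical artifacts.
#'
#' @param config An `"epicpcrRunConfig"` list from [runConfig()] or
#'   [loadRunConfig()].
#' @return Invisibly, a list with `summary`, `files` and the key in-memory
#'   objects (community, detection matrix, strategy results).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "epicpcrRunConfig"))
    out <- config$outputDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    seed <- config$seed
    design <- config$design
    community <- do.call(simulateCommunity,
                         c(config$community,
                           list(seed = deriveSeed(seed, 1L))))
    bids <- batchIds(design)
    batches <- lapply(seq_along(bids), function(i)
        simulateBeadBatch(community, config$beads$nBeads,
                          config$beads$lambda,
                          seed = deriveSeed(seed, 10L + i),
                          batchId = bids[i]))
    qc <- do.call(rbind, lapply(batches, function(b) {
        r <- beadBatchQC(b)
        data.frame(batch_id = b@batchId,
                   n_empty = r@nEmpty, n_single = r@nSingle,
                   n_multi = r@nMulti)
    }))
    qcTable <- qcBeadBatches(qc, f = carrierFrequency(community))
    tables <- do.call(simulateReplicateTables,
                      c(list(batches, design, community),
                        config$replication,
                        list(seed = deriveSeed(seed, 30L))))
    reads <- do.call(emitFusedReads,
                     c(list(tables$counts, community, config$primers),
                       config$emission,
                       list(seed = deriveSeed(seed, 40L))))
    files <- list(
        config = file.path(out, "config.yaml"),
        design = file.path(out, "design.tsv"),
        bead_qc = file.path(out, "bead_qc.tsv"),
        truth_counts = file.path(out, "truth_counts.tsv"),
        capture = file.path(out, "truth_capture.tsv"),
        provenance = file.path(out, "read_provenance.tsv"))
    writeDesignTSV(design, files$design)
    utils::write.table(qcTable, files$bead_qc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeCountsTSV(tables$counts, design, files$truth_counts)
    utils::write.table(tables$truth$capture, files$capture, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(reads$provenance, files$provenance, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (config$emission$paired) {
        files$reads_r1 <- file.path(out, "reads_R1.fastq")
        files$reads_r2 <- file.path(out, "reads_R2.fastq")
        writeFastq(reads$r1, files$reads_r1)
        writeFastq(reads$r2, files$reads_r2)
        proc <- processAmplicons(
            reads$r1, design, config$primers, r2 = reads$r2,
            minLength = config$processing$minLength,
            identityThreshold = config$processing$identityThreshold,
            minsize = config$processing$minsize,
            minReads = config$processing$minReads)
    } else {
        files$reads <- file.path(out, "reads.fasta")
        writeFasta(reads$sequences, files$reads)
        proc <- processAmplicons(
            reads$sequences, design, config$primers,
            minLength = config$processing$minLength,
            identityThreshold = config$processing$identityThreshold,
            minsize = config$processing$minsize,
            minReads = config$processing$minReads)
    }
    files$otu_counts <- file.path(out, "otu_counts.tsv")
    files$detection <- file.path(out, "detection_matrix.tsv")
    files$centroids <- file.path(out, "otu_centroids.fasta")
    writeCountsTSV(proc$counts, design, files$otu_counts)
    writeDetectionMatrixTSV(proc$detection, files$detection)
    writeFasta(proc$centroids, files$centroids)
    results <- lapply(config$strategies, function(s)
        validateStrategy(proc$detection, s))
    names(results) <- config$strategies
    stratTab <- do.call(rbind, lapply(config$strategies, function(s) {
        eff <- detectionEfficiency(results[[s]])
        cbind(strategy = s, eff,
              validated = eff$probability > 0)
    }))
    files$strategies <- file.path(out, "strategy_results.tsv")
    utils::write.table(stratTab, files$strategies, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lc <- assignConfidenceLevels(proc$detection)
    files$confidence <- file.path(out, "confidence_levels.tsv")
    utils::write.table(lc, files$confidence, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cmpTech <- compareStrategies(proc$detection, "technical:2/2",
                                 "technical:3/3")
    cmpBio <- compareStrategies(proc$detection, "biological:2/2",
                                "biological:3/3")
    mcnemar <- list(
        technical_dup_vs_trip = .cmpSummary(cmpTech),
        biological_dup_vs_trip = .cmpSummary(cmpBio))
    files$mcnemar <- file.path(out, "mcnemar.json")
    jsonlite::write_json(mcnemar, files$mcnemar, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    yaml::write_yaml(.configEcho(config), files$config)
    summary <- list(
        dialect = config$dialect, seed = seed,
        preferred_strategy = config$preferredStrategy,
        min_reads = config$processing$minReads,
        n_carriers_simulated = length(carrierIds(community)),
        bead_qc_passed = sum(qcTable$passed),
        n_reads = nrow(reads$provenance),
        n_otus = length(proc$centroids),
        n_detected = length(detectedOTUs(proc$detection)),
        n_validated = lapply(results, function(r)
            length(validatedOTUs(r))),
        n_validated_preferred =
            length(validatedOTUs(results[[config$preferredStrategy]])),
        confidence_level_counts = as.list(table(factor(
            lc$level, levels = 5:1))),
        mcnemar = mcnemar)
    files$summary <- file.path(out, "summary.json")
    jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- list(
        stages = c("simulate", "process", "validate"),
        seed = seed,
        parameters = .configEcho(config),
        checksums = {
            sums <- tools::md5sum(unlist(files))
            names(sums) <- basename(unlist(files))
            as.list(sums)
        })
    files$manifest <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(summary = summary, files = files,
                   community = community, detection = proc$detection,
                   results = results, confidence = lc,
                   processing = proc))
}

.cmpSummary <- function(cmp) {
    list(b = unname(cmp$test$parameter["b"]),
         c = unname(cmp$test$parameter["c"]),
         p_value = cmp$test$p.value,
         method = cmp$test$method)
}

# Plain-list echo of a configuration (for YAML/JSON serialisation).
.configEcho <- function(config) {
    tb <- designTable(config$design)
    list(dialect = config$dialect, seed = config$seed,
         community = config$community, beads = config$beads,
         replication = config$replication, emission = config$emission,
         processing = config$processing,
         strategies = as.list(config$strategies),
         preferred_strategy = config$preferredStrategy,
         design = list(batch_id = tb$batchId,
                       replicate_id = tb$replicateId,
                       usable = tb$usable),
         primers = list(forward = config$primers@forward,
                        bridge = config$primers@bridge,
                        reverse = config$primers@reverse,
                        max_mismatches = config$primers@maxMismatches))
}
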