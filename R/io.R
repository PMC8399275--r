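#' Read and write FASTA / FASTQ files
#'
#' `readFasta()` / `writeFasta()` wrap the Biostrings readers for plain
#' (uncompressed) FASTA. `readFastq()` is a strict Sanger Phred+33 FASTQ
#' parser that reports the offending line number on malformed records;
#' `writeFastq()` writes 4-line records. `write(read(x))` round-trips
#' records exactly.
#'
#' @param path File path.
#' @param x Sequences: a [Biostrings::DNAStringSet] (`writeFasta`) or
#'   [Biostrings::QualityScaledDNAStringSet] (`writeFastq`).
#' @return `readFasta()` a [Biostrings::DNAStringSet]; `readFastq()` a
#'   [Biostrings::QualityScaledDNAStringSet]; writers return the path
#'   invisibly.
#' @name sequence-io
NULL

#' @rdname sequence-io
#' @export
readFasta <- function(path) {
    tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
             error = function(e)
                 stop("malformed FASTA '", path, "': ",
                      conditionMessage(e), call. = FALSE))
}

#' @rdname sequence-io
#' @export
writeFasta <- function(x, path) {
    Biostrings::writeXStringSet(x, path, format = "fasta")
    invisible(path)
}

#' @rdname sequence-io
#' @export
readFastq <- function(path) {
    if (!file.exists(path))
        stop("FASTQ file not found: '", path, "'", call. = FALSE)
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
        stop("malformed FASTQ '", path, "': truncated record at line ",
             length(lines), call. = FALSE)
    n <- length(lines) / 4
    hdr <- lines[seq(1, by = 4, length.out = n)]
    seq <- lines[seq(2, by = 4, length.out = n)]
    plus <- lines[seq(3, by = 4, length.out = n)]
    qual <- lines[seq(4, by = 4, length.out = n)]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad))
        stop("malformed FASTQ '", path, "': missing '@' at line ",
             (bad[1] - 1) * 4 + 1, call. = FALSE)
    bad <- which(!startsWith(plus, "+"))
    if (length(bad))
        stop("malformed FASTQ '", path, "': missing '+' at line ",
             (bad[1] - 1) * 4 + 3, call. = FALSE)
    bad <- which(nchar(seq) != nchar(qual))
    if (length(bad))
        stop("malformed FASTQ '", path,
             "': sequence/quality length mismatch at line ",
             (bad[1] - 1) * 4 + 2, call. = FALSE)
    s <- Biostrings::DNAStringSet(seq)
    names(s) <- sub("^@", "", hdr)
    Biostrings::QualityScaledDNAStringSet(
        s, Biostrings::PhredQuality(qual))
}

#' @rdname sequence-io
#' @export
writeFastq <- function(x, path) {
    stopifnot(is(x, "QualityScaledDNAStringSet"))
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    writeLines(as.vector(rbind(paste0("@", ids), as.character(x), "+",
                               as.character(Biostrings::quality(x)))),
               path)
    invisible(path)
}

#' Read and write replicate-design TSV files
#'
#' Columns `batch_id`, `replicate_id`, `usable` (TRUE/FALSE or 1/0); any
#' unknown column is a parse error.
#'
#' @param path File path.
#' @param design A [ReplicateDesign-class].
#' @return `readDesignTSV()` a [ReplicateDesign-class]; the writer
#'   returns the path invisibly.
#' @name design-io
NULL

#' @rdname design-io
#' @export
readDesignTSV <- function(path) {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("batch_id", "replicate_id", "usable")
    extra <- setdiff(names(tb), need)
    if (length(extra))
        stop("unknown column(s) in design '", path, "': ",
             paste(extra, collapse = ", "), call. = FALSE)
    if (!all(need %in% names(tb)))
        stop("design '", path, "' must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
    ReplicateDesign(batchId = tb$batch_id, replicateId = tb$replicate_id,
                    usable = as.logical(tb$usable))
}

#' @rdname design-io
#' @export
writeDesignTSV <- function(design, path) {
    tb <- designTable(design)
    utils::write.table(
        data.frame(batch_id = tb$batchId, replicate_id = tb$replicateId,
                   usable = tb$usable),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write OTU count / detection matrices as TSV
#'
#' Layout: comment lines `#batch<TAB>...` (batch id per replicate column)
#' and, for detection matrices, `#min_reads<TAB>n`; then a header line
#' `otu_id` followed by one column per replicate id.
#'
#' @param path File path.
#' @param counts Integer matrix, OTUs x replicates.
#' @param dm A [DetectionMatrix-class].
#' @param design A [ReplicateDesign-class] (reader only; when omitted, a
#'   design is reconstructed from the batch comment line with all
#'   replicates usable).
#' @return Readers return a matrix (`readCountsTSV`) or
#'   [DetectionMatrix-class] (`readDetectionMatrixTSV`); writers return
#'   the path invisibly.
#' @name matrix-io
NULL

.writeMatrixTSV <- function(m, batches, path, minReads = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("#batch", batches), collapse = "\t"), con)
    if (!is.null(minReads) && !is.na(minReads))
        writeLines(paste("#min_reads", minReads, sep = "\t"), con)
    writeLines(paste(c("otu_id", colnames(m)), collapse = "\t"), con)
    utils::write.table(m, con, sep = "\t", quote = FALSE,
                       col.names = FALSE, row.names = TRUE)
    invisible(path)
}

.readMatrixTSV <- function(path) {
    if (!file.exists(path))
        stop("matrix file not found: '", path, "'", call. = FALSE)
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    body <- grep("^#", lines, value = TRUE, invert = TRUE)
    if (length(body) < 1L)
        stop("matrix '", path, "': no header line", call. = FALSE)
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    if (header[1] != "otu_id")
        stop("matrix '", path, "': first column must be otu_id ",
             "(line ", length(meta) + 1, ")", call. = FALSE)
    reps <- header[-1]
    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    bad <- which(lengths(rows) != length(header))
    if (length(bad))
        stop("matrix '", path, "': wrong field count at line ",
             length(meta) + 1 + bad[1], call. = FALSE)
    m <- matrix(0L, length(rows), length(reps),
                dimnames = list(vapply(rows, `[`, character(1), 1), reps))
    for (i in seq_along(rows))
        m[i, ] <- as.integer(rows[[i]][-1])
    batchLine <- grep("^#batch\t", meta, value = TRUE)
    batches <- if (length(batchLine))
        strsplit(batchLine[1], "\t", fixed = TRUE)[[1]][-1] else reps
    mrLine <- grep("^#min_reads\t", meta, value = TRUE)
    minReads <- if (length(mrLine))
        as.integer(strsplit(mrLine[1], "\t")[[1]][2]) else NA_integer_
    list(matrix = m, batches = batches, minReads = minReads)
}

#' @rdname matrix-io
#' @export
writeCountsTSV <- function(counts, design, path) {
    us <- usableReplicates(design)
    batches <- us$batchId[match(colnames(counts), us$replicateId)]
    .writeMatrixTSV(counts, batches, path)
}

#' @rdname matrix-io
#' @export
readCountsTSV <- function(path) .readMatrixTSV(path)$matrix

#' @rdname matrix-io
#' @export
writeDetectionMatrixTSV <- function(dm, path) {
    stopifnot(is(dm, "DetectionMatrix"))
    .writeMatrixTSV(SummarizedExperiment::assay(dm, "detected"),
                    unname(replicateBatches(dm)), path,
                    minReads = minReadsThreshold(dm))
}

#' @rdname matrix-io
#' @export
readDetectionMatrixTSV <- function(path, design = NULL) {
    parsed <- .readMatrixTSV(path)
    if (is.null(design))
        design <- ReplicateDesign(batchId = parsed$batches,
                                  replicateId = colnames(parsed$matrix))
    DetectionMatrix(parsed$matrix, design, minReads = parsed$minReads)
}
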