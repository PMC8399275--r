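Package: epicpcr2
Title: Bead Occupancy Modelling, Fused-Amplicon Processing and
    Replicate-Based OTU Validation for epicPCR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for emulsion, paired isolation and
    concatenation PCR (epicPCR) experiments, which link a functional
    marker gene to the 16S rRNA gene of its host inside single-cell
    polyacrylamide beads. Provides Poisson occupancy statistics and
    pass/fail quality rules for bead batches, a bespoke processing chain
    for fused target+16S amplicon reads (pair merging, length filtering,
    bridge-primer splitting, dereplication, greedy abundance-ordered
    centroid OTU clustering and read mapping), and a replicate-strategy
    validation framework that scores OTUs by their detection probability
    across technical or biological replicate combinations, tests
    dependence between strategies with McNemar's test, and assigns
    ordinal confidence levels. A seeded simulator generates communities
    with rare target-carrier taxa, Poisson bead loading, batch-level
    carrier capture, amplification dropout and fused reads, so the whole
    pipeline can be exercised end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bead-model.R'
    'cli.R'
    'cluster-otus.R'
    'design.R'
    'emit-reads.R'
    'experiments.R'
    'io.R'
    'merge-pairs.R'
    'pipeline.R'
    'simulate-community.R'
    'simulate-replicates.R'
    'split-reads.R'
    'utils.R'
    'validate.R'
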