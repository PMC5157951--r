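Package: hoxcis
Title: Cis-Acting Transcriptional Consequences of a Hox-Cluster lncRNA Deletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-usable pipeline for analysing the local (cis) versus distant
    (trans) transcriptional consequences of deleting an antisense lncRNA locus
    (Hotair) inside a Hox gene cluster. Provides strand-aware gene-level read
    counting over flattened exon models, RPKM computation with a rank-stability
    median-scaling normalization, negative-binomial GLM likelihood-ratio tests
    of genotype effects with joint Benjamini-Hochberg correction, promoter-based
    H3K27me3/input Polycomb-target calling with satellite-repeat exclusion,
    quantification of read-through transcription across deletion breakpoints
    (Ghostair, AntiHotair, long AntiHotair), and exploratory statistics
    (centred PCA, Euclidean sample clustering, replicate correlations, GO
    background-list construction, contingency-table chi-square tests). A
    synthetic-data module generates annotation, stranded alignments, coverage
    and ChIP/input tracks with planted effects so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    methods,
    MASS,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
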