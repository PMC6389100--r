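Package: promarch
Title: Promoter Architecture Analysis from CAGE Transcription Start Site Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing promoter architecture from CAGE (cap
    analysis of gene expression) transcription start site data across
    developmental stages. CTSS counts are normalized to tags per million,
    clustered into per-stage tag clusters with dominant-position and
    interquantile-width statistics, classified into sharp/broad shape and
    CpG-content classes, and merged into cross-stage consensus promoter
    regions whose expression profiles are grouped with a self-organizing
    map. Promoter shifts between stages are detected with a
    cumulative-distribution shifting score and a Kolmogorov-Smirnov test
    under FDR control. Position-specific core promoter motifs (exhaustive
    k-mer positional enrichment, fixed-window IUPAC searches, dinucleotide
    profiles and PWM scans) are analysed around dominant TSSs. Promoters
    are assigned to gene models and operons, spliced-leader trans-spliced
    genes are classified, operon-internal promoters are found, and
    motif-driven exclusion of trans-splice acceptor sites is detected.
    Tiling-array log-ratios are normalized with a Tukey biweight mean,
    smoothed with a running median, and summarized as metagene profiles
    around dominant TSSs with bootstrap confidence intervals. A synthetic
    data generator with planted, machine-readable ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
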