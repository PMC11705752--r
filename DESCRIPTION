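Package: promoMethyl
Title: Alternative Promoter CpG Methylation, Epiallele Patterns and
    First-Exon Usage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for targeted (amplicon) bisulfite sequencing analysis of
    alternative promoter regions: parsing per-read CpG methylation calls,
    per-site methylated-read fractions with coverage, bisulfite conversion
    QC from non-CpG context, read-level epiallele (methylation pattern)
    frequency analysis and pattern sharing between related samples,
    differential methylation between sublines, site-by-site and
    methylation-versus-expression Spearman correlation with
    Benjamini-Hochberg correction, transcription factor binding site
    overlap, expression-matched background-region construction and
    phyloP-based conservation comparison (delta-phyloP), relative
    first-exon usage quantification in tumour cohorts with clustering and
    survival stratification (Kaplan-Meier, log-rank, Cox), and a synthetic
    data generator that emulates the statistical structure of all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    survival,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, Coverage, Survival, Software
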