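Package: comparetox
Title: COMPARE-Style Pharmacogenomics of Drug Sensitivity in Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating drug response to transcriptome profiles across
    a panel of tumor cell lines, in the tradition of the NCI COMPARE approach.
    From per-cell-line log10(IC50) values and a genes-by-lines expression
    matrix, the package ranks genes by Pearson correlation with the response
    profile, selects a top-k positive/negative resistance signature, clusters
    cell lines on the signature by the Ward method with clustered-image-map
    export, and tests the cluster/sensitivity association by chi-square.
    Supporting stages cover four-parameter logistic IC50 estimation from
    viability curves with degree-of-resistance ratios, strand-aware promoter
    extraction with position-weight-matrix log-odds scanning and a
    dinucleotide-shuffle motif enrichment z-score, and gene-set
    over-representation by Fisher's right-tailed exact test with curated
    functional-group network assembly. A synthetic-data generator plants
    correlated genes, promoter motifs, and dose-response curves so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    Biostrings,
    minpack.lm,
    igraph,
    ape,
    pheatmap,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
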