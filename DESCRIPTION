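Package: molitoR
Title: Read-Weighted GO Enrichment and Temporal Expression Analysis of the
    Tenebrio molitor Gut Response to Cry3Aa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the transcriptional response of the
    Tenebrio molitor larval gut to Bacillus thuringiensis Cry3Aa protoxin.
    Implements a read-abundance- and contig-length-weighted Fisher's exact
    test for Gene Ontology functional enrichment of assembled transcriptome
    contigs (alongside the classical contig-presence test), with
    Benjamini-Hochberg FDR control and a filter cascade (fold change,
    minimum contig count, child-term pruning, score restriction); a
    two-colour temporal microarray differential-expression stage (mean
    scaling, per-time t tests, all-times ANOVA, Venn overlaps, PCA and
    Manhattan/average-linkage clustering); a delta-delta-Ct qPCR stage with
    reference-gene normalisation; an OBO ontology subset reader with
    true-path annotation propagation; and seeded synthetic-data generators
    that emulate the study design so every stage is testable without the
    original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
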