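Package: cismotif
Title: Condition-Specific Transcription Factors and Cis-Acting Element
    Discovery from Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies condition-specific transcription factors (CsTFs)
    from multi-condition expression matrices by differential-expression
    testing and a cross-condition z-score of fold change, builds
    co-expressed gene groups by Pearson correlation, and infers candidate
    cis-acting elements on the promoters of each group by
    background-calibrated hypergeometric enrichment of all 4-8-mer
    motifs (presence and occurrence-number modes). Enriched 8-mers
    carrying over-represented 3-/4-mer cores are mapped back onto group
    promoters, overlapping occurrences are merged, and position-specific
    scoring matrices (PSSMs) with information-content logo matrices are
    assembled; reverse-complement palindromes (e.g. the heat-shock
    element GAAnnTTC) are classified and TSS-distance bias is profiled.
    Includes a seeded synthetic-data generator for expression matrices,
    condition designs, genomes and promoters with planted structure, and
    an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
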