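Package: kleptoscreen
Title: Multi-Evidence Screening for Algal Horizontal Gene Transfer in
    Kleptoplastic Sea-Slug Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to screen an animal genome assembly for algae-derived
    horizontal gene transfer (HGT) and to nominate kleptoplasty-related
    host genes. Implements bit-score HGT indices (h and hA), MEGAN-style
    lowest-common-ancestor taxonomic assignment of BLAST-type hit tables,
    alignment- and read-level homology credibility screens, scaffold
    decontamination by gene content and coverage depth, orthogroup
    expansion Z-scores with Fisher exact enrichment of differentially
    expressed genes, and small physiology statistics (oxygen-rate
    regression and Welch's t-test). A fully seeded synthetic-data
    generator plants ground-truth HGT genes, contaminant and organelle
    scaffolds so every stage of the screen can be exercised and validated
    end-to-end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Genetics, Sequencing, Annotation, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
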