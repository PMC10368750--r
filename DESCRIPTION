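Package: lncSieve
Title: Consensus-Based Long Non-Coding RNA Discovery, Positional
    Classification and Cross-Morphotype Annotation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring long non-coding RNA (lncRNA) catalogues
    from de novo eye transcriptome assemblies of the two Astyanax
    mexicanus morphotypes (cavefish and surface fish), generalised to any
    pair of transcript sets. Implements a five-tool coding-potential
    consensus vote (4-of-5 with an undetermined class), the candidate
    filtering cascade (length, consensus, protein/ncRNA annotation,
    identity-1.0 redundancy removal, expression floor), a 16-class
    positional classifier of lncRNA-gene geometry with best-partner
    selection and a six-way GENCODE-style summary, reciprocal-best-hit
    sharing between morphotypes, EST in-silico validation, tiered
    conservation annotation with known/novel partitioning, a two-round
    fish conservation screen, and candidate-gene interaction reporting.
    A synthetic-data module generates every pipeline input with planted
    ground truth so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, Annotation, Classification, Sequencing
RoxygenNote: 7.3.3
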