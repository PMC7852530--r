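Package: denovotrio
Title: De Novo Variant Detection, Annotation and Enrichment Analysis in
    Parent-Offspring Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying de novo variants (DNVs) in whole-genome
    sequenced parent-offspring trios where the child is affected by a complex
    disease such as systemic lupus erythematosus. Implements
    Mendelian-inconsistency candidate detection with genotype-posterior,
    allele-balance and external-score filters; functional annotation of DNVs
    against gene models, chromatin states, DNase hypersensitive sites and
    transcription-factor binding site tracks with a GC-content exclusion
    filter; case-versus-control enrichment statistics (ratio of proportions,
    Pearson chi-squared, Bonferroni correction, expected excess and patient
    occupancy expectations); read-backed parent-of-origin phasing and
    paternal-age regression; a dual-caller reciprocal-overlap consensus
    procedure for de novo structural variants with parental subtraction,
    annotation exclusion and flanking-coverage filtering; and a fully
    deterministic synthetic trio-cohort generator with a ground-truth ledger
    so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
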