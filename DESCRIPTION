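Package: srdk
Title: Small RNA and Degradome Analysis of Plant miRNAs, Phased siRNAs and
    SSR Co-Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a plant small-RNA / degradome
    analysis pipeline: collapsing and filtering of small-RNA libraries with
    TPM normalization and cross-tissue comparison, hairpin secondary-structure
    prediction by base-pair maximization, known and novel miRNA discovery from
    stem-loop precursors with miRNA* evidence, degradome (PARE) T-plot target
    calling with category I/II/III confidence classification, prediction of
    21-nt phased secondary siRNAs triggered by 22-nt miRNAs, detection of
    simple sequence repeats and their co-localization with miRNA precursors,
    and a fully self-contained synthetic-data generator with ground-truth
    manifests for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
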