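Package: plasmaclone
Title: Clonality, Copy Number and Mutational Signature Analysis of ctDNA Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of circulating tumour DNA (ctDNA) targeted-sequencing
    variant calls in advanced cancer cohorts. Provides germline filtering and
    pathogenicity classification of plasma variant calls, cancer-fraction and
    clonal-dominance estimation from variant allele frequencies, polyclonality
    summaries, purity-adjusted plasma copy number with ROC evaluation against
    tissue labels, co-occurrence and clinical-association contingency
    statistics with false-discovery-rate control, 96-channel trinucleotide
    mutation catalogues with non-negative signature exposure fitting and
    bootstrap comparison of clonal versus subclonal mutation sets, APOBEC
    consensus-site classification, and a seeded synthetic-cohort generator
    with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    pROC,
    jsonlite
Config/testthat/edition: 3
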