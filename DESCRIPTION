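Package: igtls
Title: Classification of Ig V-Lambda Hypermutation Events and
    Translesion-Synthesis Bypass Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-classification and count-statistics pipeline for
    somatic hypermutation and translesion-synthesis (TLS) assays in the
    chicken DT40 B-cell line.  Aligns sequenced Ig V-lambda clones to the
    parental segment, calls mutations, and assigns each to a non-templated
    point mutation (PM), a long-tract gene conversion (GC) against a
    pseudogene donor array, or an ambiguous (Amb) event using a
    minimum-donor-string rule.  Classifies replicated copies of
    site-specific T-T (6-4) photoproduct plasmids (staggered and opposing
    lesion arrangements) into bypass modes and builds per-position
    nucleotide-incorporation profiles.  Provides Poisson rate estimates
    for chromosomal aberration counts, Mann-Whitney U comparisons of
    sister chromatid exchange samples, and a synthetic-data generator with
    truth labels so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
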