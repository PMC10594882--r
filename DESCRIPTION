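Package: cardiacg2p
Title: Gene-Disease Knowledge Base and Mechanism-Aware Variant Filtering for Inherited Cardiac Conditions
Version: 0.1.0
Authors@R: person("Cardiac", "G2P Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A structured, machine-readable knowledge base of curated gene-disease
    pairs for inherited cardiac conditions (cardiomyopathies and arrhythmia
    syndromes), recording inheritance, allelic requirement, disease-associated
    variant consequences and disease-relevant variant classes, together with
    gene-specific restricted repertoires of pathogenic alleles. Implements three
    rare-variant prioritisation pipelines over VEP-annotated VCFs - a generic
    protein-altering-variant filter, a LOFTEE/ClinVar filter, and the
    mechanism- and allelic-requirement-aware G2P filter - plus an evaluation
    harness (sensitivity with binomial confidence intervals, positive rate, and
    two-sided Fisher exact pipeline comparisons) and a deterministic synthetic
    fixture generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
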