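Package: VariantTriage
Title: Candidate-Gene Variant Triage, Cohort Allele Aggregation and
    Interaction Clustering for Small Rare-Disease Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing annotated candidate-gene variants in
    small whole-exome cohorts. Implements a composite in-silico
    deleteriousness classifier (SIFT / PolyPhen2 / MutationAssessor
    consensus for missense variants; CADD PHRED and LoF-Tool rules for
    loss-of-function and splice classes), per-patient compound
    heterozygosity and X-linked hemizygosity bookkeeping, binomial
    allele-aggregation statistics against reference population
    frequencies, exact 2x2 testing, Markov Clustering of weighted
    protein-interaction networks with a degree-preserving permutation
    enrichment test, and a fully seeded synthetic-cohort generator so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
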