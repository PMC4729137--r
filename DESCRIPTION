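Package: ampvar
Title: Low-Frequency Mutation Detection in Ultra-Deep Amplicon Sequencing of
    Circulating Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an ultra-deep amplicon sequencing
    pipeline for detecting low-frequency somatic substitutions in circulating
    cell-free DNA (cfDNA), as used to monitor androgen receptor (AR)
    ligand-binding-domain mutations in castration-resistant prostate cancer.
    Provides a seeded read simulator with regime-dependent amplification noise
    (native vs whole-genome-amplified libraries), quality-filtered per-position
    base counting, an outlier-statistic variant caller with regime-specific
    frequency floors, a cohort recurrent-artifact filter and patient-linked
    call rescue, read-backed haplotype frequency estimation, codon-level
    protein annotation, four-parameter logistic dose-response fitting with
    censoring, an agonist-conversion classifier, and a packaged
    mutation-to-drug response knowledge base for therapy reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    Rsamtools,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
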