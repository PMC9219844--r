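Package: duomics
Title: Dual-Omics Integration of Metabolite and Transcript Evidence for
    Dysregulated Metabolic Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating untargeted LC-MS metabolomics with RNA-seq
    transcriptomics at the level of Enzyme Commission (EC) codes. Provides
    molecular-formula parsing and monoisotopic mass arithmetic, ppm-tolerance
    adduct annotation of LC-MS features against an offline compound registry,
    retention-time alignment and Welch/BH differential-abundance testing,
    a simplified median-of-ratios differential-expression stage for count
    matrices, derivation of EC sets independently from the metabolite layer
    (compound-to-EC associations) and the transcript layer (PFAM-to-EC
    associations), intersection of the two sets to call dual-evidence
    dysregulated reactions, permutation-based pathway activity scoring, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
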