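Package: medstatus
Title: Sentence-Level Medical Status Extraction from Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotation-efficient pipeline for extracting per-condition
    patient status (present, absent, former, unknown) from unstructured
    clinical documents by sentence classification. Provides deterministic
    sentence segmentation, rule-based preannotation with negation, family
    context and cessation cue scoping, density-aware corpus qualification
    with bias-assessment statistics, Cohen's kappa agreement gating and
    correction management, class-weighted multinomial training of a hashed
    n-gram linear classifier, deduplicated stratified cross-validation with
    per-document-type breakdown and patient-overlap audit, an iterative
    refinement loop, and a synthetic French clinical-corpus generator with
    exported gold labels so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
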