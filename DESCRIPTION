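Package: rbaselect
Title: Harmonized Selection of Components for Food Risk-Benefit Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tiered, auditable engine for selecting the nutritional,
    microbiological, and toxicological components of a food risk-benefit
    assessment (RBA). Candidate components move through three lists: a long
    list assembled from the compositional profiles of the two foods being
    compared (with a concentration-difference rule for nutrients and an
    evidence-level gate), a short list selected by an occurrence-by-severity
    prioritization index built from graded 1-3 sub-criteria, and a final list
    gated on a data-availability checklist, with a nutrient symmetry rule for
    substitution scenarios. Every inclusion and exclusion decision is recorded
    in a selection ledger. Ships the beef-versus-cricket substitution case
    study as a machine-readable fixture and a seeded synthetic-profile
    generator with an independent scoring oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
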