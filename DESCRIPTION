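Package: karyocohort
Title: Karyotype Parsing and Cohort Analysis for Prenatal Cytogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing amniotic-fluid karyotype cohorts. Parses a
    clinically oriented subset of ISCN 2016 karyotype nomenclature into typed
    clone/abnormality objects, classifies each result on four hierarchical
    levels (mosaicism, structural class, chromosome involvement, balance
    status), counts non-centromeric chromosome breakage events, maps clinical
    screening records to the twelve standard prenatal-diagnosis indication
    groups, tabulates detection rates by year, indication, chromosome and
    category, and provides a searchable store of classified karyotypes. A
    seeded synthetic-cohort generator reproduces the categorical structure of
    a large amniocentesis series so the whole pipeline can be exercised and
    validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
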