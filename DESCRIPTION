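Package: pvscreen
Title: Disproportionality Screening of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    adverse-event reporting streams of the FAERS kind. Parses quarterly
    delimited DEMO/DRUG/REAC/INDI tables, assembles and deduplicates case
    reports, maps drug names to ATC codes and adverse events to MedDRA-style
    preferred-term sets, builds report-level 2x2 contingency tables against
    the full-database background, and screens drug-event pairs with the
    reporting odds ratio (Wald 95% CI) and the shrinkage information
    component, applying a joint signal criterion. Includes a
    confounding-by-indication sensitivity reanalysis that excludes reports
    carrying co-existing seizure-prone conditions, Table-1 style demographic
    descriptives, and a fully seeded synthetic report generator with planted
    relative reporting rates and an analytic expected reporting odds ratio
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
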