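Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("FAERS", "Signal Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pharmacovigilance analysis of the FDA
    Adverse Event Reporting System (FAERS): ingestion of the quarterly
    "$"-delimited ASCII tables, case assembly, removal of FDA-deleted cases,
    two-stage report deduplication, age validation, primary-suspect cohort
    selection via drug-name dictionaries, mapping of reaction Preferred Terms
    to user-supplied SOC/SMQ term lists, disproportionality statistics
    (proportional reporting ratio, reporting odds ratio, Pearson chi-square,
    Bayesian information component with credibility bounds), time-to-onset
    summaries under date-validity rules, and Table-1 style cohort
    descriptives.  Includes a synthetic FAERS corpus generator with a
    ground-truth ledger so the whole pipeline is testable without any
    download, and a command-line entry point that orchestrates the stages
    from a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
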