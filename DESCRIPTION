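Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("FAERS", "Signal Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FDA Adverse Event Reporting System (FAERS) style quarterly ASCII files.
    Reads and validates the DEMO/DRUG/REAC/THER/OUTC/INDI datasets,
    deduplicates case versions by the FDA-recommended CASEID/FDA_DT/PRIMARYID
    rule, classifies index-drug reports into treatment-regimen subgroups via a
    configurable drug lexicon, computes reporting odds ratios (ROR) with 95%
    confidence intervals and positive-signal flags, and summarises
    time-to-onset and demographic/outcome characteristics. Ships a synthetic
    FAERS generator with known ground-truth association structure so the whole
    pipeline is testable without downloading FAERS.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
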