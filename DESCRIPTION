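Package: incidose
Title: Incidental Nodal Dose, Equivalent Uniform Dose and Tumour Control
    Probability Analysis for Involved-Field Radiotherapy Plans
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the incidental radiation dose deposited in
    out-of-field (elective) hilar and mediastinal lymph node stations by
    involved-field radiotherapy plans for non-small-cell lung cancer.
    Provides dose-grid and dose-volume-histogram (DVH) data structures with
    the usual plan-quality metrics (Dmean, Dmax, Dx, Vx, conformation
    number), the generalized equivalent uniform dose (EUD, a power mean of
    dose), a logistic tumour control probability (TCP) model for
    microscopic disease, organ-at-risk constraint checking with a 2-Gy
    prescription escalation loop and fraction-matched plan normalization,
    AJCC nodal-station grouping rules (all-elective and adjacent-elective
    volumes), paired cohort statistics with a normality-gated test router,
    and a synthetic paired IMRT / 3D-conformal cohort generator so the full
    pipeline can be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
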