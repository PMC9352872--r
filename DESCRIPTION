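Package: cmllines
Title: Lines of Therapy, Resource Use, and Costs from CML Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construct lines of therapy for chronic myeloid leukemia in
    chronic phase (CML-CP) from administrative pharmacy and medical claims,
    apply a cohort-selection cascade (diagnosis, washout, enrollment,
    approval-date and exclusion-code criteria), and compute descriptive
    treatment-pattern, healthcare-resource-utilization, and
    per-patient-per-month cost outcomes for third-or-later lines of therapy.
    Includes a synthetic longitudinal claims generator with ground-truth
    treatment trajectories so every stage of the pipeline can be validated
    without access to proprietary claims databases, plus publication-style
    table formatting with small-cell suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
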