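Package: methylfluid
Title: Forensic Body Fluid Identification from CpG Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based identification of seven forensically relevant body
    fluids (nasal secretion, nasal blood, peripheral blood, menstrual blood,
    saliva, vaginal secretion, sperm secretion) from bisulfite-pyrosequencing
    methylation percentages at a six-CpG marker panel (NB21, B7, MB4, SA4, V2,
    N27SE), conditioned on rapid pre-test results for blood, saliva and sperm.
    Includes duplicate-measurement quality control, gap-based cutoff
    calibration, a tiered-threshold classifier with mixture and
    partial-component calls, sensitivity/specificity validation reports, and a
    synthetic cohort generator that reproduces the published per-fluid
    methylation distributions for end-to-end testing without real casework
    samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
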