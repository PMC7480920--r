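Package: trialpower
Title: Power and Sample-Size Comparison of Longitudinal Biomarkers in
    Early Alzheimer's Disease Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares longitudinal biomarkers (plasma neurofilament light,
    structural MRI composites, cognitive composites) as outcome measures for
    clinical trials of preclinical and mild Alzheimer's disease. Builds
    diagnostic groups from long-format visit tables (amyloid PET SUVR
    intercepts, CSF Abeta42, Clinical Dementia Rating), fits random-intercept/
    random-slope linear mixed models per biomarker and group with nlme,
    converts the fitted variance components and slopes into the per-arm sample
    size required to detect a fractional slowing of progression, sweeps trial
    duration and sampling frequency, and quantifies uncertainty by
    subject-level bootstrap. Includes a synthetic longitudinal cohort
    generator with ADNI-like visit schedules, monotone dropout and
    per-modality missingness, and a Monte-Carlo power simulator that serves
    as an independent check on the closed-form sample-size formula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
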