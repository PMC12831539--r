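Package: practicefx
Title: Practice-Effect Change Scores and Long-Term Cognitive Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies one-year practice effects on a nine-test
    neuropsychological battery with standardized regression-based (SRB)
    change scores fitted on a normative control cohort, classifies
    cognitive status from education-corrected MoCA scores, derives
    time-to-onset of cognitive impairment and dementia, and runs the
    accompanying inferential battery: group comparisons of SRB z-scores,
    chi-square tests on reliable-change categories, Cox
    proportional-hazards prognosis models with Schoenfeld diagnostics,
    Benjamini-Hochberg false discovery rate correction, and median-split
    cumulative-incidence curves. Includes a seeded synthetic longitudinal
    cohort generator with known ground truth for end-to-end validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
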