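Package: fuzzycad
Title: Fuzzy Expert System for Grading Anatomical Coronary Artery Lesions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A Mamdani-style fuzzy rule-based classifier for assessing the
    degree of anatomical coronary artery lesions in patients with coronary
    artery disease. Provides a reusable fuzzy-inference engine (piecewise
    linear and generalised bell membership functions, min/product t-norms,
    max/probabilistic-sum s-norms, centre-of-gravity defuzzification), the
    complete published clinical knowledge base (four angiographic lesion
    factors with five linguistic terms each and a fourteen-rule base mapping
    them to four clinical forms of coronary artery disease), least-squares
    tuning of membership parameters and rule weights, a seeded synthetic
    cohort generator matching the published group statistics, and CSV/JSON
    input-output utilities with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
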