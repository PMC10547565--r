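Package: kneemetric
Title: A Common Item Response Theory Metric for the Oxford Knee Score and
    High Activity Arthroplasty Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Places the Oxford Knee Score (OKS) and the High Activity
    Arthroplasty Score (HAAS) on a common latent "knee health" metric with
    a graded response model. Provides fixed-parameter (anchored) marginal
    maximum likelihood calibration by an EM algorithm, pattern and
    summed-score expected a posteriori (EAP) scoring via the
    Lord-Wingersky recursion, sum-score conversion and crosswalk tables,
    item and test information curves with the information-to-reliability
    approximation, an item response theory assumption-testing battery
    (Cronbach's alpha, disattenuated correlation, Mokken scalability,
    Yen's Q3 local dependence, ordinal-logistic differential item
    functioning, Bland-Altman agreement), and a synthetic-cohort
    generator with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    MASS,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
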