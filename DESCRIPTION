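Package: mitotick
Title: Epigenetic Mitotic Clock Analysis for Hematopoietic DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores DNA methylation beta matrices with the epiTOC epigenetic
    mitotic clock (pcgtAge), derives age-residualized mitotic-age acceleration
    (AccelEpiTOC) and related acceleration measures (AgeAccel, IEAA, EEAA),
    estimates leukocyte composition by reference-based constrained projection,
    and fits the composition-adjusted association and symptom-progression
    models used in hematopoietic mitotic-aging studies.  Ships a synthetic
    hematopoietic methylome generator (purified-cell panels, whole-blood
    case-control mixtures with composition confounding, longitudinal exam
    scores) with ground truth for parameter-recovery benchmarking, and an
    orchestrator that runs the full simulate-score-deconvolve-model pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
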