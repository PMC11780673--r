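Package: ehrsigneval
Title: Evaluation of Clinical-Sign Extraction from Free-Text Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating automated extraction of binary clinical
    signs from free-text electronic health records against a
    multi-annotator human reference. Provides sensitivity-based sample
    size calculation, corpus filtering, prompt construction and
    structured-output parsing with conservative repair, mode-based
    consensus, diagnostic performance metrics with Wilson score
    confidence intervals, pairwise Cohen's kappa reproducibility,
    McNemar's paired comparison, verbatim citation auditing with a
    normalization ladder and hallucination detection, an error taxonomy
    over model-versus-consensus disagreements, and a fully seeded
    synthetic generator of corpora, human annotator panels, and repeated
    machine-annotator runs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
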