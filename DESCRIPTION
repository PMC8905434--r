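Package: cogseg
Title: Cognitive-Unit Text Segmentation and Eye-Fixation Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns a lexicon of cognitive units (subword, word, and
    multiword chunks) from raw text with the unsupervised Less-is-Better
    learner, which segments character input under a least-effort objective
    using larger-first selection and counterfactual evaluation.  Includes a
    backward-transitional-probability chunk learner as a comparator, two
    word-based baselines, a center-of-unit linking rule that converts any
    segmentation into per-word predicted first-pass eye-fixation counts, a
    weighted-F1 evaluation suite with Skip/One/More confusion summaries,
    and a seeded synthetic-corpus generator for end-to-end testing without
    external eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
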