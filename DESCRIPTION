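Package: procoder
Title: Procedure Code Assignment from Clinical Short Text by
    Translate-and-Match
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns controlled procedure codes (anesthesiology CPT-style,
    5-character identifiers) to short, noisy operative free text in two
    steps: a compact encoder-decoder Transformer translates the manually
    entered procedure text into the canonical preferred-term description
    of a code, and an inverse-distance transformation step (1/(x+1) over
    Levenshtein and token-Jaccard distances) matches the top beam-search
    candidates against the full code catalog to predict codes by argmax.
    Includes the text-curation pipeline, a TF-IDF bigram SVM baseline,
    date-based holdout and label-stratified splitting, top-1/top-3
    accuracy with bootstrap confidence intervals, corpus BLEU, a
    sample-size-group sensitivity analysis for imbalanced labels, and a
    seeded synthetic generator of catalogs and operative-case corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
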