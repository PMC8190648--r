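# procoder

Automated assignment of anesthesia procedure codes to the short, noisy
free text of operative records, for researchers and billing-informatics
teams who need a transparent alternative to black-box multiclass
classifiers.

Each operative case carries a surgeon-typed procedure description
(~5 words, with misspellings, acronyms and shorthand) and a
preoperative diagnosis (~4 words); billing requires exactly one code
from a controlled vocabulary in which every code has a single canonical
description (*preferred term*, ~13 words). `procoder` solves the
assignment in two steps:

1. **Translate.** A compact encoder-decoder Transformer (implemented in
   RcppArmadillo) is trained on pairs (noisy text, preferred term of
   the gold code) and beam-search decodes the top-3 candidate
   descriptions for each new case.
2. **Match.** Each candidate is scored against the preferred term of
   every catalog code with a string distance *x* — character
   Levenshtein, token Jaccard, or the mean of the two inverse scores —
   mapped through the inverse-distance similarity

   *s* = 1 / (*x* + 1) ∈ (0, 1],

   merged over candidates by maximum, and the code is predicted by
   argmax (ties to the smallest code).

Around this core the package provides the text-curation pipeline
(stopwords, spelling, acronym expansion, lemmatization), date-based
holdout and label-stratified splits, a TF-IDF bigram linear-SVM
baseline, the evaluation protocol (top-1/top-3 accuracy, 500-rep
percentile-bootstrap CIs, corpus BLEU, ten sample-size groups for
imbalanced labels), and a fully seeded synthetic generator of code
catalogs and operative-case corpora, since real registry data cannot be
shared.

## Worked example

Fifty codes, 2,400 synthetic cases with moderate noise (10% per-token
misspelling, 10% dropout, acronym compression), date cutoff 2019-02-01:

```r
library(procoder)

catalog <- make_catalog(50, seed = 101)
sim  <- simulate_cases(catalog, synth_config(n_codes = 50,
                                             n_cases = 2400, seed = 101))
lex  <- synth_lexicons(catalog)
sp   <- date_split(sim$cases, "2019-02-01")
pairs <- build_pairs(sp$development, catalog, "curated", lex)
hold  <- build_pairs(sp$holdout,     catalog, "curated", lex)

model <- nmt_train(pairs, nmt_config(seed = 101))   # ~2 min, 1 CPU
cands <- translate(model, hold$source, k = 3)
preds <- predict_codes(score_matrix(cands, catalog, "mean"))

topk_accuracy(preds, hold$code, 1)
#> [1] 0.95
topk_accuracy(preds, hold$code, 3)
#> [1] 0.9805556
hyp <- vapply(cands, function(x) x$candidates$sentence[1], character(1))
corpus_bleu(hyp, hold$target)
#> [1] 0.9727761
```

Top-1 = 0.95 means the argmax code matched the gold code for 95% of
the 360 held-out cases; top-3 is the share where the gold code is among
the three suggestions a coder would review; BLEU ≈ 0.97 says the
decoded descriptions are near-verbatim preferred terms. Appending the
(informative) synthetic diagnoses — `mode = "curated+diagnosis"` —
raises top-1 further, for the SVM baseline as well as for the
translation pipeline.

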