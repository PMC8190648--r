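test_that("synthetic catalogs are valid, distinct and reproducible", {
  cat1 <- make_catalog(60, seed = 4)
  cat2 <- make_catalog(60, seed = 4)
  expect_identical(cat1$entries, cat2$entries)
  expect_identical(attr(cat1, "synth")$phrase, attr(cat2, "synth")$phrase)
  expect_equal(nrow(cat1$entries), 60)
  expect_false(anyDuplicated(cat1$entries$preferred_term) > 0)
  expect_false(anyDuplicated(attr(cat1, "synth")$phrase) > 0)
  # every generated code falls inside a named body-region range
  expect_false(any(category_of(cat1, cat1$entries$code) == "uncategorized"))
  tiny <- make_catalog(2, seed = 1)
  expect_equal(nrow(tiny$entries), 2)
})

test_that("preferred-term lengths emulate controlled-vocabulary scale", {
  cat <- make_catalog(200, seed = 9)
  len <- lengths(strsplit(cat$entries$preferred_term, " ", fixed = TRUE))
  expect_gte(mean(len), 11)
  expect_lte(mean(len), 15)
})

test_that("simulated corpora are deterministic and replayable", {
  cat <- make_catalog(30, seed = 2)
  cfg <- synth_config(n_codes = 30, n_cases = 400, seed = 6)
  s1 <- simulate_cases(cat, cfg)
  s2 <- simulate_cases(cat, cfg)
  expect_identical(s1$cases, s2$cases)
  # replaying the recorded operators reproduces every emitted text
  expect_identical(replay_truth(s1$truth), s1$cases$procedure_text)
  expect_identical(s1$truth$code, s1$cases$code)
  d <- as.Date(s1$cases$date)
  expect_true(all(d >= as.Date("2017-01-01") & d <= as.Date("2019-06-30")))
})

test_that("zero noise emits canonical phrases verbatim", {
  cat <- make_catalog(30, seed = 2)
  cfg <- synth_config(n_codes = 30, n_cases = 300, misspell_rate = 0,
                      acronym_rate = 0, token_dropout_rate = 0,
                      reorder_rate = 0, seed = 3)
  sim <- simulate_cases(cat, cfg)
  expect_identical(sim$cases$procedure_text, sim$truth$canonical)
  expect_true(all(lengths(sim$truth$ops) == 0))
})

test_that("label frequencies follow the designed long-tailed law", {
  cat <- make_catalog(50, seed = 8)
  cfg <- synth_config(n_codes = 50, n_cases = 2000, seed = 8)
  sim <- simulate_cases(cat, cfg)
  cnt <- table(factor(sim$cases$code, levels = cat$entries$code))
  cnt <- sort(as.integer(cnt), decreasing = TRUE)
  # histogram non-increasing in designed rank, top 20% carry >= 70%
  expect_false(is.unsorted(rev(cnt)))
  expect_gte(sum(cnt[1:10]) / sum(cnt), 0.70)
})

test_that("emitted text lengths track the registry statistics", {
  cat <- make_catalog(60, seed = 5)
  cfg <- synth_config(n_codes = 60, n_cases = 1500, seed = 5)
  sim <- simulate_cases(cat, cfg)
  len <- lengths(strsplit(sim$cases$procedure_text, " ", fixed = TRUE))
  expect_gte(mean(len), 3.5)
  expect_lte(mean(len), 6.5)
  dlen <- lengths(strsplit(sim$cases$preop_diagnosis, " ", fixed = TRUE))
  expect_gte(mean(dlen), 2.5)
  expect_lte(mean(dlen), 5.5)
})

test_that("misspelling noise increases edit distance monotonically", {
  cat <- make_catalog(40, seed = 3)
  dist_at <- vapply(c(0, 0.1, 0.3), function(r) {
    cfg <- synth_config(n_codes = 40, n_cases = 600, misspell_rate = r,
                        acronym_rate = 0, token_dropout_rate = 0,
                        reorder_rate = 0, seed = 7)
    sim <- simulate_cases(cat, cfg)
    mean(levenshtein(sim$cases$procedure_text, sim$truth$canonical))
  }, numeric(1))
  expect_equal(dist_at[1], 0)
  expect_lt(dist_at[1], dist_at[2])
  expect_lt(dist_at[2], dist_at[3])
})

test_that("synthetic lexicons expand the generator's acronyms", {
  cat <- make_catalog(40, seed = 3)
  lex <- synth_lexicons(cat)
  acr <- attr(cat, "synth")$acronyms
  expect_gt(length(acr), 0)
  a1 <- names(acr)[1]
  expect_equal(normalize_text(a1, lex, steps = c("lowercase", "acronym")),
               unname(acr[1]))
  cfg <- synth_config(n_codes = 40, n_cases = 1500, misspell_rate = 0,
                      acronym_rate = 1, token_dropout_rate = 0,
                      reorder_rate = 0, seed = 2)
  sim <- simulate_cases(cat, cfg)
  compressed <- sim$cases$procedure_text != sim$truth$canonical
  expect_gt(mean(compressed), 0.5)
  # normalization undoes the acronym compression
  restored <- normalize_text(sim$cases$procedure_text[compressed], lex,
                             steps = c("trim", "lowercase", "acronym"))
  expect_identical(restored, sim$truth$canonical[compressed])
})

test_that("invalid generator settings are rejected", {
  expect_error(synth_config(misspell_rate = 1.4), "rates")
  expect_error(synth_config(n_codes = 1), "n_codes")
  expect_error(synth_config(n_codes = 100, n_cases = 50), "n_cases")
  cat <- make_catalog(10, seed = 1)
  expect_error(simulate_cases(cat, synth_config(n_codes = 20,
                                                n_cases = 100)),
               "does not match")
  expect_error(simulate_cases(toy_catalog(),
                              synth_config(n_codes = 4, n_cases = 10)),
               "make_catalog")
})

test_that("synthetic corpus files land on disk as plain text", {
  cat <- make_catalog(10, seed = 1)
  sim <- simulate_cases(cat, synth_config(n_codes = 10, n_cases = 40,
                                          seed = 1))
  dir <- withr::local_tempdir()
  write_synth_corpus(cat, sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "catalog.tsv", "cases.jsonl", "acronyms.tsv", "stopwords.txt",
    "truth.jsonl")))))
  back <- read_cases(file.path(dir, "cases.jsonl"))
  expect_equal(back$procedure_text, sim$cases$procedure_text)
  expect_identical(load_catalog(file.path(dir, "catalog.tsv"))$entries,
                   cat$entries)
})
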