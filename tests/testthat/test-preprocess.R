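test_that("whitespace and case normalization", {
  expect_equal(normalize_text("  Right  Kidney Transplant ",
                              steps = c("trim", "lowercase")),
               "right kidney transplant")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text(NA_character_), "")
})

test_that("lexicon lookups expand acronyms and correct spellings", {
  lex <- normalization_lexicons(
    spelling = c(transplnt = "transplant"),
    acronyms = c(ect = "electroconvulsive therapy"))
  expect_equal(normalize_text("ect", lex), "electroconvulsive therapy")
  expect_equal(normalize_text("transplnt", lex), "transplant")
  # acronym expansion precedes spelling correction, so expansions are
  # themselves curated
  lex2 <- normalization_lexicons(
    spelling = c(theraphy = "therapy"),
    acronyms = c(ect = "electroconvulsive theraphy"))
  expect_equal(normalize_text("ect", lex2), "electroconvulsive therapy")
})

test_that("stopword removal and lemmatization apply after lexicons", {
  lex <- normalization_lexicons(stopwords = c("for", "the", "on"))
  expect_equal(normalize_text("Anesthesia for procedures on the eye", lex),
               "anesthesia procedure eye")
})

test_that("lexicon validation catches degenerate maps", {
  expect_error(normalization_lexicons(spelling = c(knee = "knee")),
               "maps to itself")
  expect_error(normalization_lexicons(acronyms = c(ect = " ")),
               "non-empty")
  expect_error(normalize_text("x", steps = "shout"), "unknown step")
})

test_that("normalization is idempotent for fixed-point-free lexicons", {
  lex <- normalization_lexicons(
    stopwords = c("of", "the"),
    spelling = c(transplnt = "transplant"),
    acronyms = c(tka = "total knee arthroplasty"))
  inputs <- c("Revision of TKA, left;", "  TRANSPLNT  of the Kidney ",
              "plain text already", "tka tka")
  once <- normalize_text(inputs, lex)
  expect_identical(normalize_text(once, lex), once)
})

test_that("normalization only grows token counts via acronym expansion", {
  lex <- normalization_lexicons(stopwords = c("of", "the"),
                                spelling = c(kneee = "knee"))
  inputs <- c("excision of the kneee lesion", "biopsy, deep; of lesion",
              "one", "")
  count_tokens <- function(x) {
    x <- trimws(gsub("[[:space:]]+", " ", gsub("[^[:alnum:] ]", " ", x)))
    if (!nzchar(x)) 0L else length(strsplit(x, " ", fixed = TRUE)[[1]])
  }
  for (x in inputs) {
    n_in <- count_tokens(x)
    out <- normalize_text(x, lex)
    n_out <- if (nzchar(out)) length(strsplit(out, " ")[[1]]) else 0
    expect_lte(n_out, max(n_in, 0))
  }
})

test_that("input modes mirror the three experimental settings", {
  case <- data.frame(procedure_text = "Right total knee arthroplasty",
                     preop_diagnosis = "knee arthritis",
                     stringsAsFactors = FALSE)
  expect_equal(build_input(case, "curated+diagnosis"),
               "right total knee arthroplasty knee arthritis")
  raw <- data.frame(procedure_text = "Lt PHACO  IOL",
                    preop_diagnosis = "", stringsAsFactors = FALSE)
  expect_identical(build_input(raw, "raw"), "Lt PHACO  IOL")
  # empty diagnosis degrades mode 3 to mode 2, with a warning
  expect_warning(m3 <- build_input(raw, "curated+diagnosis"),
                 "missing a preoperative diagnosis")
  expect_identical(m3, build_input(raw, "curated"))
})

test_that("mode-3 token count is mode-2 plus the diagnosis tokens", {
  cases <- data.frame(
    procedure_text = c("Right total knee arthroplasty", "ECT session"),
    preop_diagnosis = c("severe knee arthritis", "depression"),
    stringsAsFactors = FALSE)
  lex <- normalization_lexicons(stopwords = "severe")
  n2 <- lengths(strsplit(build_input(cases, "curated", lex), " "))
  nd <- lengths(strsplit(normalize_text(cases$preop_diagnosis, lex), " "))
  n3 <- lengths(strsplit(build_input(cases, "curated+diagnosis", lex), " "))
  expect_equal(n3, n2 + nd)
})

test_that("lexicon and stopword files round trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ect\telectroconvulsive therapy", "tka\ttotal knee"), p)
  lx <- read_lexicon(p)
  expect_identical(lx[["ect"]], "electroconvulsive therapy")
  sw <- default_stopwords()
  expect_true("the" %in% sw)
  expect_false(any(duplicated(sw)))
})
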