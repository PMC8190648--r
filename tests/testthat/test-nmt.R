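# Tiny corpora: enough to exercise training, decoding and the
# determinism contract without long runtimes.

tiny_pairs <- function(n = 30, seed = 5) {
  words <- c("knee", "hip", "lens", "scalp", "colon", "uterus", "wrist",
             "ankle", "spine", "chest", "repair", "biopsy", "excision",
             "fusion", "drainage", "left", "right")
  with_seed(seed, {
    src <- character(n); tgt <- character(n)
    for (i in seq_len(n)) {
      w <- sample(words, 3)
      src[i] <- paste(w, collapse = " ")
      tgt[i] <- paste(c("anesthesia", "for", w, "procedure"),
                      collapse = " ")
    }
    unique(data.frame(case_id = as.character(seq_len(n)), code = "00100",
                      source = src, target = tgt,
                      stringsAsFactors = FALSE))
  })
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

tiny_config <- function(epochs = 120, seed = 7) {
  nmt_config(embed_dim = 32, layers = 2, heads = 4, ffn_dim = 64,
             max_len = 16, beam_size = 5, epochs = epochs, seed = seed)
}

test_that("an overfit model memorizes its training targets", {
  pairs <- tiny_pairs()
  model <- nmt_train(pairs, tiny_config())
  # loss decreases over the first epochs
  expect_lt(mean(tail(model$loss, 3)), model$loss[1])
  cands <- translate(model, pairs$source, k = 1)
  hyp <- vapply(cands, function(x) x$candidates$sentence[1], character(1))
  expect_gte(mean(hyp == pairs$target), 0.95)
})

test_that("decoding is deterministic and scores are non-increasing", {
  pairs <- tiny_pairs()
  cfg <- tiny_config(epochs = 40)
  m1 <- nmt_train(pairs, cfg)
  m2 <- nmt_train(pairs, cfg)
  expect_identical(m1$params, m2$params)
  c1 <- translate(m1, pairs$source[1:8], k = 3)
  c2 <- translate(m2, pairs$source[1:8], k = 3)
  expect_identical(lapply(c1, `[[`, "candidates"),
                   lapply(c2, `[[`, "candidates"))
  for (tc in c1) {
    expect_true(all(diff(tc$candidates$score) <= 1e-12))
    expect_true(all(nzchar(tc$candidates$sentence)))
    expect_lte(nrow(tc$candidates), 3)
    expect_false(any(duplicated(tc$candidates$sentence)))
  }
  # decoding is pure: repeated calls agree
  expect_identical(translate(m1, pairs$source[1], k = 3),
                   translate(m1, pairs$source[1], k = 3))
})

test_that("training and decoding validate their inputs", {
  pairs <- tiny_pairs()
  expect_error(nmt_train(pairs[0, ], tiny_config()), "empty")
  long <- pairs
  long$target[3] <- paste(rep("word", 30), collapse = " ")
  expect_error(nmt_train(long, tiny_config()), "max_len.*3")
  model <- nmt_train(pairs[1:10, ], tiny_config(epochs = 5))
  expect_error(translate(model, pairs$source[1], k = 9), "beam_size")
  expect_error(translate(model, pairs$source[1], k = 0), "at least 1")
  expect_error(translate(model, "   "), "empty source")
  expect_error(nmt_config(embed_dim = 30, heads = 4), "divisible")
})

test_that("unknown source tokens fall back to a single unknown symbol", {
  pairs <- tiny_pairs()
  model <- nmt_train(pairs, tiny_config(epochs = 40))
  # never-seen tokens decode without error
  out <- translate(model, "zzz qqq", k = 1)
  expect_s3_class(out[[1]], "translation_candidates")
  expect_true(nzchar(out[[1]]$candidates$sentence[1]))
})

test_that("checkpoints round trip through save and load", {
  pairs <- tiny_pairs(n = 12)
  model <- nmt_train(pairs, tiny_config(epochs = 30))
  dir <- withr::local_tempdir()
  save_nmt(model, dir)
  expect_true(all(file.exists(file.path(dir, c("config.json", "vocab.txt",
                                               "weights.bin")))))
  back <- load_nmt(dir)
  expect_identical(back$vocab, model$vocab)
  expect_equal(back$params, model$params)
  expect_identical(translate(back, pairs$source[1:4], k = 2),
                   translate(model, pairs$source[1:4], k = 2))
})
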