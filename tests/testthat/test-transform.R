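test_that("edit distance matches definitional recursion and adist", {
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("abc", "abc"), 0L)
  expect_equal(levenshtein("", "abc"), 3L)
  expect_equal(levenshtein("abc", ""), 3L)
  set.seed(1)
  pool <- vapply(1:60, function(i)
    paste(sample(letters[1:5], sample(0:8, 1), TRUE), collapse = ""),
    character(1))
  a <- sample(pool, 40, TRUE); b <- sample(pool, 40, TRUE)
  expect_equal(levenshtein(a, b),
               mapply(lev_oracle, a, b, USE.NAMES = FALSE))
  expect_equal(levenshtein(a, b),
               as.integer(mapply(utils::adist, a, b, USE.NAMES = FALSE)))
})

test_that("edit distance is symmetric and satisfies the triangle inequality", {
  set.seed(2)
  s <- vapply(1:15, function(i)
    paste(sample(c("a", "b", "c"), sample(1:6, 1), TRUE), collapse = ""),
    character(1))
  for (i in 1:15) for (j in 1:15) {
    dij <- levenshtein(s[i], s[j])
    expect_equal(dij, levenshtein(s[j], s[i]))
    k <- (i + j) %% 15 + 1
    expect_lte(dij, levenshtein(s[i], s[k]) + levenshtein(s[k], s[j]))
  }
})

test_that("token Jaccard distance follows set arithmetic", {
  expect_equal(jaccard_distance("knee joint", "joint knee"), 0)
  expect_equal(jaccard_distance("a b", "c d"), 1)
  expect_equal(jaccard_distance("a b", "b c"), 2 / 3)
  expect_equal(jaccard_distance("", ""), 0)
  expect_equal(jaccard_distance("a a a b", "a b"), 0)  # sets, not bags
  set.seed(3)
  words <- c("knee", "hip", "repair", "left", "right", "biopsy", "lens")
  for (i in 1:50) {
    ta <- sample(words, sample(0:5, 1))
    tb <- sample(words, sample(0:5, 1))
    expected <- if (!length(union(ta, tb))) 0 else
      1 - length(intersect(ta, tb)) / length(union(ta, tb))
    expect_equal(jaccard_distance(paste(ta, collapse = " "),
                                  paste(tb, collapse = " ")), expected)
  }
})

test_that("inverse-distance scores obey the 1/(x+1) algebra", {
  cat <- toy_catalog()
  terms <- normalize_text(cat$entries$preferred_term,
                          steps = c("trim", "lowercase"))
  sm <- score_matrix(list(terms[1]), cat, metric = "levenshtein")
  expect_equal(unname(sm$scores[1, 1]), 1)  # exact match, distance 0
  # one character off: distance 1, score 1/2
  sm1 <- score_matrix(list(sub("^a", "b", terms[1])), cat,
                      metric = "levenshtein")
  expect_equal(unname(sm1$scores[1, 1]), 0.5)
  # all scores in (0, 1]
  sm_all <- score_matrix(as.list(c("knee", "eye lens", "zzz")), cat,
                         metric = "mean", keep_per_candidate = TRUE)
  expect_true(all(sm_all$scores > 0 & sm_all$scores <= 1))
  expect_true(all(sm_all$per_candidate > 0 & sm_all$per_candidate <= 1))
  # mean metric averages the two inverse scores, not the distances
  a <- "knee repair"; b <- terms[4]
  sl <- 1 / (levenshtein(a, b) + 1)
  sj <- 1 / (jaccard_distance(a, b) + 1)
  smm <- score_matrix(list(a), cat, metric = "mean")
  expect_equal(unname(smm$scores[1, 4]), (sl + sj) / 2)
})

test_that("candidate merging takes the per-label maximum", {
  cat <- toy_catalog()
  terms <- normalize_text(cat$entries$preferred_term,
                          steps = c("trim", "lowercase"))
  sm <- score_matrix(list(c(terms[2], "distant text")), cat,
                     metric = "jaccard", keep_per_candidate = TRUE)
  expect_equal(unname(sm$scores[1, 2]), 1)
  expect_equal(sm$scores[1, ], apply(sm$per_candidate, 2, max),
               ignore_attr = TRUE)
})

test_that("score matrix validates inputs", {
  cat <- toy_catalog()
  expect_error(score_matrix(list(character(0)), cat), "zero candidates")
  empty_cat <- toy_catalog()
  empty_cat$entries <- empty_cat$entries[0, ]
  expect_error(score_matrix(list("x"), empty_cat), "empty")
})

test_that("argmax prediction recovers exact matches and breaks ties low", {
  cat <- toy_catalog()
  terms <- normalize_text(cat$entries$preferred_term,
                          steps = c("trim", "lowercase"))
  pr <- predict_codes(score_matrix(as.list(terms), cat, metric = "mean"))
  expect_equal(pr$top1, cat$entries$code)
  expect_true(all(pr$top1_score == 1))
  # single-label catalog predicts that label for anything
  one <- code_catalog("00104", "Anesthesia for electroconvulsive therapy")
  pr1 <- predict_codes(score_matrix(list("totally unrelated"), one))
  expect_equal(pr1$top1, "00104")
  # exact ties resolve to the smallest code
  tie <- code_catalog(c("00200", "00105"), c("abc", "abd"))
  prt <- predict_codes(score_matrix(list("ab"), tie, metric = "levenshtein"))
  expect_equal(prt$top1, "00105")
})

test_that("top-3 keeps beam order, deduplicates, pads, contains top-1", {
  cat <- toy_catalog()
  terms <- normalize_text(cat$entries$preferred_term,
                          steps = c("trim", "lowercase"))
  # three candidates all matching the same label: padding fills to 3
  pr <- predict_codes(score_matrix(list(rep(terms[3], 3)), cat))
  expect_equal(pr$top3[[1]][1], cat$entries$code[3])
  expect_equal(length(pr$top3[[1]]), 3)
  expect_false(any(duplicated(pr$top3[[1]])))
  # candidates matching distinct labels keep beam order
  pr2 <- predict_codes(score_matrix(list(c(terms[2], terms[1])), cat))
  expect_equal(pr2$top3[[1]][1:2], cat$entries$code[c(2, 1)])
  expect_true(pr2$top1[1] %in% pr2$top3[[1]])
})

test_that("prediction is invariant to catalog label order", {
  cat <- toy_catalog()
  perm <- c(3, 1, 4, 2)
  cat_perm <- code_catalog(cat$entries$code[perm],
                           cat$entries$preferred_term[perm])
  queries <- list("knee arthroplasty", "kidney transplant recipient",
                  "electroconvulsive", "eye lens")
  p1 <- predict_codes(score_matrix(queries, cat, metric = "mean"))
  p2 <- predict_codes(score_matrix(queries, cat_perm, metric = "mean"))
  expect_equal(p1$top1, p2$top1)
  expect_equal(p1$top3, p2$top3)
})
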