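test_that("top-k accuracy counts hits within the first k predictions", {
  pred <- rbind(c("00104", "00142", "00868"),
                c("00142", "00104", "00868"),
                c("00868", "00142", "00104"))
  truth <- c("00104", "00104", "00104")
  expect_equal(topk_accuracy(pred, truth, 1), 1 / 3)
  expect_equal(topk_accuracy(pred, truth, 3), 1)
  expect_gte(topk_accuracy(pred, truth, 3), topk_accuracy(pred, truth, 1))
  # truth always in position 2: top-1 zero, top-3 one
  pred2 <- rbind(c("00142", "00104", "00868"), c("00868", "00104", "00142"))
  expect_equal(topk_accuracy(pred2, c("00104", "00104"), 1), 0)
  expect_equal(topk_accuracy(pred2, c("00104", "00104"), 3), 1)
  expect_error(topk_accuracy(pred, truth[1:2], 1), "differ in length")
})

test_that("bootstrap intervals bracket the point estimate deterministically", {
  set.seed(5)
  truth <- sample(c("00104", "00142"), 300, TRUE)
  pred <- truth
  flip <- sample(300, 60)
  pred[flip] <- ifelse(pred[flip] == "00104", "00142", "00104")
  ci <- bootstrap_ci(pred, truth, k = 1, reps = 500, seed = 11)
  expect_equal(ci$point, 0.8)
  expect_lte(ci$low, ci$point)
  expect_gte(ci$high, ci$point)
  ci2 <- bootstrap_ci(pred, truth, k = 1, reps = 500, seed = 11)
  expect_identical(ci, ci2)
  # all-correct input gives a degenerate (1, 1) interval
  cip <- bootstrap_ci(truth, truth, k = 1, reps = 100, seed = 1)
  expect_equal(c(cip$point, cip$low, cip$high), c(1, 1, 1))
  expect_error(bootstrap_ci(character(0), character(0)), "empty")
})

test_that("bootstrap width shrinks as the resample size grows", {
  set.seed(6)
  truth <- sample(c("a", "b", "c"), 5000, TRUE)
  pred <- truth
  flip <- sample(5000, 1000)
  pred[flip] <- "zzz"
  narrow <- bootstrap_ci(pred, truth, reps = 300, sample_size = 4000,
                         seed = 2)
  wide <- bootstrap_ci(pred, truth, reps = 300, sample_size = 400,
                       seed = 2)
  expect_lt(narrow$high - narrow$low, wide$high - wide$low)
})

test_that("corpus BLEU matches a hand-evaluated case and its bounds", {
  expect_equal(corpus_bleu("a b c d e", "a b c d e"), 1)
  # modified precisions 4/5, 3/4, 2/3, 1/2; brevity penalty 1;
  # (0.8 * 0.75 * 2/3 * 0.5)^(1/4) = 0.2^0.25
  expect_equal(corpus_bleu("a b c d e", "a b c d f"), 0.2^0.25)
  expect_lt(corpus_bleu(rep("x y z w v", 50), rep("a b c d e", 50)), 0.01)
  # invariant to the order of sentence pairs
  hyp <- c("a b c", "d e f g", "h i")
  ref <- c("a b d", "d e f f", "h j")
  expect_equal(corpus_bleu(hyp, ref), corpus_bleu(rev(hyp), rev(ref)))
  expect_error(corpus_bleu("a", c("a", "b")), "differ in length")
})

test_that("codes split into near-equal sample-size groups", {
  set.seed(7)
  counts <- stats::setNames(rpois(272, 40), sprintf("%05d", 1:272))
  g <- group_by_sample_size(counts, 10)
  sizes <- table(g$assignment$group)
  expect_equal(length(sizes), 10)
  expect_lte(diff(range(sizes)), 2)
  # partition: every code in exactly one group
  expect_setequal(g$assignment$code, names(counts))
  expect_false(any(duplicated(g$assignment$code)))
  # group index increases with training count
  med <- tapply(g$assignment$count, g$assignment$group, median)
  expect_true(all(diff(med) >= 0))
  # all-equal counts still give near-equal groups
  g2 <- group_by_sample_size(stats::setNames(rep(5, 30),
                                             sprintf("%05d", 1:30)), 10)
  expect_true(all(table(g2$assignment$group) == 3))
  g3 <- group_by_sample_size(counts, 1)
  expect_equal(unique(g3$assignment$group), 1)
})

test_that("per-group accuracies respect assignment and absence", {
  counts <- stats::setNames(c(1, 2, 50, 60), c("00101", "00102", "00103",
                                               "00104"))
  groups <- group_by_sample_size(counts, 2)
  truth <- c("00103", "00104", "00104")
  pred <- c("00103", "00104", "00101")
  rep1 <- per_group_report(pred, truth, groups, k = 1)
  expect_equal(nrow(rep1), 1)  # low-count group absent, not zero
  expect_equal(rep1$accuracy, 2 / 3)
  # all samples in one group: group accuracy equals overall accuracy
  expect_equal(rep1$accuracy, topk_accuracy(pred, truth, 1))
  expect_error(per_group_report("99999", "99999", groups), "not assigned")
})

test_that("evaluation reports bundle accuracy, intervals and BLEU", {
  truth <- rep(c("00104", "00142"), 20)
  pred <- cbind(truth, "00868", "01402")
  pred[1, 1] <- "00868"
  r <- eval_report(pred, truth, reps = 50, seed = 3,
                   hypotheses = c("a b c", "a b d"),
                   references = c("a b c", "a b c"))
  expect_s3_class(r, "eval_report")
  expect_equal(r$top1, 39 / 40)
  expect_gte(r$top3, r$top1)
  expect_lte(r$top1_ci$low, r$top1)
  expect_true(r$bleu > 0 && r$bleu < 1)
  expect_output(print(r), "top-1")
})
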