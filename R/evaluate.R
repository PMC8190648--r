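#' Top-k accuracy
#'
#' Fraction of samples whose gold code appears among the first `k`
#' predicted codes. Top-1 uses the single best prediction; top-3 asks
#' whether the truth is within the three best. Top-3 accuracy is never
#' below top-1 on the same predictions.
#'
#' @param predictions A [predict_codes()] result, an [svm_train_predict()]
#'   result, a character matrix (samples x ranked codes) or, for k = 1,
#'   a character vector.
#' @param truth Character vector of gold codes, same length.
#' @param k 1 or 3 (any positive k up to the prediction width works).
#' @return Proportion in \[0, 1\].
#' @export
topk_accuracy <- function(predictions, truth, k = 1) {
  mat <- prediction_matrix(predictions)
  truth <- pad_code(as.character(truth))
  if (nrow(mat) != length(truth))
    stop("predictions and truth differ in length (", nrow(mat), " vs ",
         length(truth), ")")
  k <- min(k, ncol(mat))
  hit <- vapply(seq_along(truth),
                function(i) truth[i] %in% mat[i, seq_len(k)], logical(1))
  mean(hit)
}

prediction_matrix <- function(predictions) {
  mat <- if (inherits(predictions, "code_predictions")) {
    k <- max(lengths(predictions$top3))
    m <- matrix(NA_character_, nrow(predictions), k)
    for (i in seq_len(nrow(predictions)))
      m[i, seq_along(predictions$top3[[i]])] <- predictions$top3[[i]]
    m
  } else if (inherits(predictions, "svm_baseline")) {
    predictions$codes
  } else if (is.character(predictions) && is.null(dim(predictions))) {
    matrix(predictions, ncol = 1)
  } else {
    as.matrix(predictions)
  }
  keep <- !is.na(mat)
  mat[keep] <- pad_code(mat[keep])
  mat
}

#' Bootstrap confidence interval for top-k accuracy
#'
#' The point estimate is the accuracy on the full evaluation set; the
#' interval takes the 2.5th and 97.5th percentiles of accuracies over
#' `reps` resamples of `sample_size` cases drawn with replacement
#' (percentile bootstrap at 95%). The reference protocol repeats the
#' experiment 500 times with 20,000 resampled cases; `sample_size`
#' defaults to `min(20000, n)` so small evaluation sets are not
#' oversampled pathologically. Deterministic given `seed`.
#'
#' @param predictions,truth,k As in [topk_accuracy()].
#' @param reps Number of bootstrap repetitions.
#' @param sample_size Resample size (with replacement).
#' @param seed Integer seed.
#' @return Object of class `accuracy_ci`: `point`, `low`, `high`, `n`,
#'   `reps`, `sample_size`.
#' @export
bootstrap_ci <- function(predictions, truth, k = 1, reps = 500,
                         sample_size = NULL, seed = 1) {
  stopifnot(reps >= 1)
  mat <- prediction_matrix(predictions)
  truth <- pad_code(as.character(truth))
  if (!length(truth)) stop("empty evaluation set")
  if (nrow(mat) != length(truth))
    stop("predictions and truth differ in length")
  kk <- min(k, ncol(mat))
  hit <- vapply(seq_along(truth),
                function(i) truth[i] %in% mat[i, seq_len(kk)], logical(1))
  n <- length(hit)
  sample_size <- sample_size %||% min(20000L, n)
  stopifnot(sample_size >= 1)
  accs <- with_seed(seed, vapply(seq_len(reps), function(r) {
    mean(hit[sample.int(n, sample_size, replace = TRUE)])
  }, numeric(1)))
  q <- unname(quantile(accs, c(0.025, 0.975), type = 7))
  structure(list(point = mean(hit), low = q[1], high = q[2], n = n,
                 reps = reps, sample_size = sample_size),
            class = "accuracy_ci")
}

#' @export
print.accuracy_ci <- function(x, ...) {
  cat(sprintf("accuracy %.4f (95%% CI %.4f-%.4f; n=%d, %d reps of %d)\n",
              x$point, x$low, x$high, x$n, x$reps, x$sample_size))
  invisible(x)
}

#' Corpus-level BLEU
#'
#' Standard corpus BLEU on the 0-1 scale: geometric mean of modified
#' 1- to 4-gram precisions with a brevity penalty, tokenizing on
#' whitespace. Because references here are short single sentences, a
#' zero n-gram match count is add-one smoothed
#' (`(matches + 1) / (total + 1)`); n-gram orders with no hypothesis
#' n-grams at all are dropped from the geometric mean.
#'
#' @param hypotheses Character vector of translated sentences.
#' @param references Character vector of gold sentences, same length.
#' @param max_n Largest n-gram order (4).
#' @return BLEU in \[0, 1\].
#' @export
corpus_bleu <- function(hypotheses, references, max_n = 4) {
  if (length(hypotheses) != length(references))
    stop("hypotheses and references differ in length")
  if (!length(hypotheses)) stop("empty corpus")
  hyp <- strsplit(as.character(hypotheses), " ", fixed = TRUE)
  ref <- strsplit(as.character(references), " ", fixed = TRUE)
  hyp <- lapply(hyp, function(x) x[nzchar(x)])
  ref <- lapply(ref, function(x) x[nzchar(x)])
  matches <- totals <- numeric(max_n)
  c_len <- sum(lengths(hyp))
  r_len <- sum(lengths(ref))
  ngrams <- function(tk, n) {
    if (length(tk) < n) return(character(0))
    vapply(seq_len(length(tk) - n + 1),
           function(i) paste(tk[i:(i + n - 1)], collapse = "\t"),
           character(1))
  }
  for (i in seq_along(hyp)) {
    for (n in seq_len(max_n)) {
      hg <- ngrams(hyp[[i]], n)
      if (!length(hg)) next
      rg <- ngrams(ref[[i]], n)
      totals[n] <- totals[n] + length(hg)
      if (length(rg)) {
        ht <- table(hg); rt <- table(rg)
        common <- intersect(names(ht), names(rt))
        matches[n] <- matches[n] +
          sum(pmin(ht[common], rt[common]))
      }
    }
  }
  use <- totals > 0
  if (!any(use)) return(0)
  p <- ifelse(matches[use] > 0, matches[use] / totals[use],
              (matches[use] + 1) / (totals[use] + 1))
  bp <- if (c_len >= r_len) 1 else exp(1 - r_len / c_len)
  bp * exp(mean(log(p)))
}

#' Group codes by training sample size
#'
#' Sensitivity-analysis grouping for imbalanced labels: codes are sorted
#' ascending by training-set sample count (ties by code) and cut into
#' `n_groups` near-equal-cardinality groups, the remainder spread over
#' the lowest groups. Group index increases with training sample size;
#' boundaries are recorded from the realized counts.
#'
#' @param train_counts Named integer vector or table: training sample
#'   count per code (zero allowed).
#' @param n_groups Number of groups (default 10).
#' @return Object of class `group_spec`: `assignment` (data frame
#'   `code`, `count`, `group`) and `boundaries` (per group min/max count
#'   and code cardinality).
#' @export
group_by_sample_size <- function(train_counts, n_groups = 10) {
  counts <- as.integer(train_counts)
  codes <- pad_code(names(train_counts))
  if (is.null(codes)) stop("`train_counts` must be named by code")
  n <- length(codes)
  stopifnot(n_groups >= 1, n_groups <= n)
  ord <- order(counts, codes)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  group <- rep(seq_len(n_groups), times = sizes)
  assignment <- data.frame(code = codes[ord], count = counts[ord],
                           group = group, stringsAsFactors = FALSE)
  boundaries <- do.call(rbind, lapply(split(assignment, assignment$group),
    function(g) data.frame(group = g$group[1], n_codes = nrow(g),
                           min_count = min(g$count),
                           max_count = max(g$count))))
  structure(list(assignment = assignment, boundaries = boundaries,
                 n_groups = n_groups), class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat("Sample-size groups (", x$n_groups, " groups, ",
      nrow(x$assignment), " codes)\n", sep = "")
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

#' Per-group accuracy report
#'
#' Top-k accuracy within each sample-size group of the gold codes.
#' Groups with no evaluation samples are absent from the report, not
#' zero. A truth code missing from the grouping is an error.
#'
#' @param predictions,truth,k As in [topk_accuracy()].
#' @param groups A [group_by_sample_size()] result.
#' @return Data frame `group`, `n`, `accuracy` (only non-empty groups).
#' @export
per_group_report <- function(predictions, truth, groups, k = 1) {
  stopifnot(inherits(groups, "group_spec"))
  mat <- prediction_matrix(predictions)
  truth <- pad_code(as.character(truth))
  g <- groups$assignment$group[match(truth, groups$assignment$code)]
  if (anyNA(g))
    stop("truth code(s) not assigned to any group: ",
         paste(unique(truth[is.na(g)]), collapse = ", "))
  kk <- min(k, ncol(mat))
  hit <- vapply(seq_along(truth),
                function(i) truth[i] %in% mat[i, seq_len(kk)], logical(1))
  out <- do.call(rbind, lapply(split(seq_along(truth), g), function(ix)
    data.frame(group = g[ix[1]], n = length(ix),
               accuracy = mean(hit[ix]))))
  rownames(out) <- NULL
  out[order(out$group), ]
}

#' Full evaluation report
#'
#' Bundles top-1 and top-3 accuracy with bootstrap confidence intervals,
#' optional corpus BLEU of the translation step, and an optional
#' per-group breakdown into one object.
#'
#' @param predictions,truth As in [topk_accuracy()].
#' @param reps,sample_size,seed Bootstrap settings, see [bootstrap_ci()].
#' @param hypotheses,references Optional sentence vectors for BLEU.
#' @param groups Optional [group_by_sample_size()] result.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(predictions, truth, reps = 500,
                        sample_size = NULL, seed = 1,
                        hypotheses = NULL, references = NULL,
                        groups = NULL) {
  ci1 <- bootstrap_ci(predictions, truth, 1, reps, sample_size, seed)
  ci3 <- bootstrap_ci(predictions, truth, 3, reps, sample_size, seed)
  rep <- list(top1 = ci1$point, top3 = ci3$point, top1_ci = ci1,
              top3_ci = ci3, n = ci1$n,
              bleu = if (!is.null(hypotheses))
                corpus_bleu(hypotheses, references) else NULL,
              per_group = if (!is.null(groups))
                per_group_report(predictions, truth, groups, 1) else NULL)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("top-1 %.4f (%.4f-%.4f)  top-3 %.4f (%.4f-%.4f)  n=%d\n",
              x$top1, x$top1_ci$low, x$top1_ci$high,
              x$top3, x$top3_ci$low, x$top3_ci$high, x$n))
  if (!is.null(x$bleu)) cat(sprintf("BLEU %.4f\n", x$bleu))
  if (!is.null(x$per_group)) {
    cat("per-group top-1:\n")
    print(x$per_group, row.names = FALSE)
  }
  invisible(x)
}
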