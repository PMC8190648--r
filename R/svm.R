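#' TF-IDF n-gram featurization
#'
#' Builds the baseline classifier's feature space: token n-grams
#' (bigrams, plus unigrams by default) extracted from the training
#' texts, kept only when their raw corpus frequency reaches `min_count`,
#' and weighted by term frequency-inverse document frequency with
#' L2-normalized rows. Transforming unseen text uses the training
#' vocabulary only; text sharing no feature with it yields an all-zero
#' row.
#'
#' Unigrams are included by default because one-token procedure texts
#' (the observed length range starts at 1) produce no bigram at all.
#'
#' @param texts Character vector of (already normalized) training or
#'   test texts.
#' @param min_count Minimum raw corpus frequency for a feature. The
#'   reference thresholds are 4 for procedure text alone and 15 for the
#'   combined procedure + diagnosis text at full registry scale; scale
#'   it down with the corpus.
#' @param include_unigrams Add unigrams alongside bigrams.
#' @param spec A `feature_spec` from a previous fit; when supplied,
#'   `texts` are transformed with the frozen vocabulary and idf.
#' @return List with `spec` (class `feature_spec`: `vocabulary`, `idf`,
#'   `min_count`, `include_unigrams`) and `X`, the dense sample-by-feature
#'   weight matrix.
#' @export
tfidf_featurize <- function(texts, min_count = 1, include_unigrams = TRUE,
                            spec = NULL) {
  texts <- as.character(texts)
  if (is.null(spec) && (!length(texts) || all(!nzchar(trimws(texts)))))
    stop("cannot fit features on an empty training corpus")
  toks <- strsplit(texts, " ", fixed = TRUE)
  inc_uni <- if (!is.null(spec)) spec$include_unigrams else include_unigrams
  grams <- lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    g <- if (inc_uni) tk else character(0)
    if (length(tk) >= 2)
      g <- c(g, paste(tk[-length(tk)], tk[-1], sep = "_"))
    g
  })
  if (is.null(spec)) {
    counts <- table(unlist(grams, use.names = FALSE))
    vocab <- sort(names(counts)[counts >= min_count])
    if (!length(vocab))
      stop("no feature reaches min_count = ", min_count)
    df <- table(factor(unlist(lapply(grams, unique), use.names = FALSE),
                       levels = vocab))
    n <- length(texts)
    idf <- log((1 + n) / (1 + as.numeric(df))) + 1
    spec <- structure(list(vocabulary = vocab, idf = idf,
                           min_count = min_count,
                           include_unigrams = include_unigrams),
                      class = "feature_spec")
  }
  X <- matrix(0, length(texts), length(spec$vocabulary),
              dimnames = list(NULL, spec$vocabulary))
  for (i in seq_along(grams)) {
    idx <- match(grams[[i]], spec$vocabulary)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tf <- table(idx)
      j <- as.integer(names(tf))
      w <- as.numeric(tf) * spec$idf[j]
      nrm <- sqrt(sum(w^2))
      X[i, j] <- w / nrm
    }
  }
  list(spec = spec, X = X)
}

#' Train the SVM baseline and predict top-k codes
#'
#' Linear-kernel multiclass SVM with probability calibration over TF-IDF
#' features, the comparison model for the translate-and-match pipeline.
#' When several `cost` values are given, a label-stratified 80/20
#' validation split of the training data picks the best value by top-1
#' accuracy before refitting on all training samples (a small grid
#' stands in for full grid-search cross-validation at desk scale).
#' Deterministic given `seed`.
#'
#' @param X Training feature matrix (samples x features).
#' @param labels Character vector of gold codes (at least two distinct).
#' @param X_test Test feature matrix over the same feature space.
#' @param k Number of codes to return per test sample.
#' @param cost Regularization cost grid.
#' @param seed Integer seed (probability calibration resamples).
#' @return List of class `svm_baseline`: `codes` (test x k matrix, best
#'   first, ties by smaller code), `prob` (matching probabilities),
#'   `cost` (selected value), `model` (the fitted e1071 object).
#' @export
svm_train_predict <- function(X, labels, X_test, k = 3, cost = 1,
                              seed = 1) {
  labels <- pad_code(as.character(labels))
  if (length(unique(labels)) < 2)
    stop("training set must contain at least two distinct labels")
  stopifnot(nrow(X) == length(labels), ncol(X_test) == ncol(X))
  if (length(cost) > 1) {
    df <- data.frame(code = labels, idx = seq_along(labels),
                     stringsAsFactors = FALSE)
    sp <- stratified_split(df, val_fraction = 0.2, seed = seed)
    acc <- vapply(cost, function(cc) {
      fit <- with_seed(seed, e1071::svm(
        X[sp$train$idx, , drop = FALSE], factor(labels[sp$train$idx]),
        kernel = "linear", cost = cc, probability = TRUE, scale = FALSE))
      pr <- with_seed(seed, attr(
        predict(fit, X[sp$validation$idx, , drop = FALSE],
                probability = TRUE), "probabilities"))
      mean(colnames(pr)[max.col(pr, ties.method = "first")] ==
             labels[sp$validation$idx])
    }, numeric(1))
    cost <- cost[which.max(acc)]
  }
  fit <- with_seed(seed, e1071::svm(X, factor(labels), kernel = "linear",
                                    cost = cost, probability = TRUE,
                                    scale = FALSE))
  prob <- with_seed(seed, attr(predict(fit, X_test, probability = TRUE),
                               "probabilities"))
  # order columns by code so probability ties resolve to the smaller code
  prob <- prob[, order(colnames(prob)), drop = FALSE]
  k <- min(k, ncol(prob))
  top <- t(apply(prob, 1, function(p) order(-p)[seq_len(k)]))
  codes <- matrix(colnames(prob)[top], nrow = nrow(prob))
  pmat <- matrix(prob[cbind(rep(seq_len(nrow(prob)), k), as.vector(top))],
                 nrow = nrow(prob))
  structure(list(codes = codes, prob = pmat, cost = cost, model = fit),
            class = "svm_baseline")
}

#' @export
print.svm_baseline <- function(x, ...) {
  cat("Linear SVM baseline: cost =", x$cost, ";",
      nrow(x$codes), "test samples, top-", ncol(x$codes),
      " codes each\n", sep = "")
  invisible(x)
}
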