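#' Character-level Levenshtein distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`. Symmetric, satisfies the
#' triangle inequality, zero iff the strings are equal. Vectorized with
#' recycling.
#'
#' @param a,b Character vectors (empty strings allowed).
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  cpp_levenshtein(as.character(a), as.character(b))
}

#' Token-set Jaccard distance
#'
#' One minus the Jaccard similarity of the whitespace-token sets of the
#' two strings: `1 - |T(a) n T(b)| / |T(a) u T(b)|`. Two empty token
#' sets have distance 0.
#'
#' @param a,b Character vectors (recycled).
#' @return Numeric vector in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  cpp_jaccard(as.character(a), as.character(b))
}

metric_code <- function(metric) {
  match(match.arg(metric, c("levenshtein", "jaccard", "mean")),
        c("levenshtein", "jaccard", "mean")) - 1L
}

# Accept translate() output, a bare list of character vectors, or a
# single character vector (one candidate per sample).
candidate_list <- function(candidates) {
  if (inherits(candidates, "translation_candidates"))
    candidates <- list(candidates)
  if (is.character(candidates)) candidates <- as.list(candidates)
  lapply(candidates, function(x) {
    if (inherits(x, "translation_candidates")) x$candidates$sentence
    else as.character(x)
  })
}

#' Inverse-distance similarity scores against the catalog
#'
#' The transformation step: every candidate translation of every sample
#' is scored against the normalized preferred term of every catalog code
#' with the chosen string distance `x`, converted to a similarity by the
#' inverse-distance map `1/(x + 1)` (so scores lie in (0, 1\] and equal
#' 1 exactly at distance 0), and the per-sample, per-label score is the
#' maximum over that sample's candidates. `metric = "mean"` averages the
#' Levenshtein and Jaccard inverse scores (not the distances), keeping
#' both the character-level and the token-level signal.
#'
#' @param candidates List with one element per sample: a
#'   `translation_candidates` object from [translate()] or a character
#'   vector of candidate sentences in beam order.
#' @param catalog A non-empty [code_catalog()].
#' @param metric `"mean"` (default), `"levenshtein"` or `"jaccard"`.
#' @param keep_per_candidate Keep the raw per-candidate score block (an
#'   `n_candidates x n_labels` matrix plus a sample index) for audit.
#' @return Object of class `code_scores`: merged `scores` matrix
#'   (samples x labels), `codes` in catalog order, and per-candidate
#'   best-label bookkeeping used for top-3 assembly.
#' @export
score_matrix <- function(candidates, catalog,
                         metric = c("mean", "levenshtein", "jaccard"),
                         keep_per_candidate = FALSE) {
  stopifnot(inherits(catalog, "code_catalog"))
  if (!nrow(catalog$entries)) stop("catalog is empty")
  metric <- match.arg(metric)
  cand <- candidate_list(candidates)
  n_cand <- lengths(cand)
  if (any(n_cand == 0))
    stop("sample(s) with zero candidates: ",
         paste(which(n_cand == 0), collapse = ", "))
  flat <- unlist(cand, use.names = FALSE)
  sample_of <- rep(seq_along(cand), n_cand)
  terms <- normalize_term(catalog$entries$preferred_term)
  block <- cpp_score_block(flat, terms, metric_code(metric))
  codes <- catalog$entries$code
  m <- length(cand)
  scores <- matrix(0, m, ncol(block), dimnames = list(NULL, codes))
  # per-candidate best label, ties broken by smallest code string
  code_rank <- order(order(codes))  # rank of each column's code
  best_lab <- integer(nrow(block))
  best_score <- numeric(nrow(block))
  for (i in seq_len(nrow(block))) {
    r <- block[i, ]
    mx <- max(r)
    tied <- which(r == mx)
    best_lab[i] <- tied[which.min(code_rank[tied])]
    best_score[i] <- mx
    s <- sample_of[i]
    scores[s, ] <- pmax(scores[s, ], r)
  }
  structure(list(
    scores = scores, codes = codes, n_samples = m,
    n_labels = length(codes), metric = metric,
    cand_sample = sample_of, cand_best = best_lab,
    cand_best_score = best_score,
    per_candidate = if (keep_per_candidate) block else NULL
  ), class = "code_scores")
}

#' @export
print.code_scores <- function(x, ...) {
  cat("Inverse-distance score matrix:", x$n_samples, "samples x",
      x$n_labels, "labels (metric:", x$metric, ")\n")
  invisible(x)
}

#' Predict codes from a score matrix
#'
#' The top-1 prediction for sample i is the label of the maximal merged
#' score (argmax over the inverse-distance matrix), ties broken by the
#' lexicographically smallest code. The top-3 list takes each candidate
#' translation's best-matching label in beam order, deduplicates
#' preserving order, and pads from the merged-score ranking when fewer
#' than three distinct labels remain; it always contains the top-1 code.
#'
#' @param scores A [score_matrix()] result.
#' @param ids Optional sample identifiers.
#' @return Data frame of class `code_predictions`: `sample_id`, `top1`,
#'   `top1_score`, `top3` (list column of up to three distinct codes,
#'   beam order) and `topk` (pipe-joined form of `top3`).
#' @export
predict_codes <- function(scores, ids = NULL) {
  stopifnot(inherits(scores, "code_scores"))
  m <- scores$n_samples
  codes <- scores$codes
  code_ord <- order(codes)
  code_rank <- order(code_ord)
  ids <- ids %||% seq_len(m)
  top1 <- character(m); top1_score <- numeric(m)
  top3 <- vector("list", m)
  for (s in seq_len(m)) {
    r <- scores$scores[s, ]
    mx <- max(r)
    tied <- which(r == mx)
    top1_idx <- tied[which.min(code_rank[tied])]
    top1[s] <- codes[top1_idx]
    top1_score[s] <- mx
    cand_rows <- which(scores$cand_sample == s)
    lead <- unique(codes[scores$cand_best[cand_rows]])
    if (length(lead) < 3 && length(codes) > length(lead)) {
      # merged ranking: by score descending, ties by smaller code
      ord <- order(-r, code_rank)
      pad <- setdiff(codes[ord], lead)
      lead <- c(lead, pad)
    }
    top3[[s]] <- head(lead, 3)
  }
  out <- data.frame(sample_id = ids, top1 = top1,
                    top1_score = top1_score, stringsAsFactors = FALSE)
  out$top3 <- top3
  out$topk <- vapply(top3, paste, character(1), collapse = "|")
  class(out) <- c("code_predictions", "data.frame")
  out
}

#' @export
print.code_predictions <- function(x, ...) {
  cat("Code predictions for", nrow(x), "samples\n")
  print(head(data.frame(sample_id = x$sample_id, top1 = x$top1,
                        top1_score = round(x$top1_score, 4),
                        top3 = x$topk), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
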