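#' Build the paired translation corpus
#'
#' Pairs each case's model input (the source sentence) with the
#' normalized preferred term of its gold code (the target sentence), the
#' way bilingual sentence pairs are assembled for translation training.
#' Target-side normalization mirrors source curation but keeps function
#' words: lowercase, punctuation stripped, whitespace collapsed, so both
#' sides live in one text space.
#'
#' @param cases Data frame of operative cases (`case_id`, `date`,
#'   `procedure_text`, `preop_diagnosis`, `code`). Run [filter_cases()]
#'   first: an unknown code is an error naming the case.
#' @param catalog A [code_catalog()].
#' @param mode Input mode, see [build_input()].
#' @param lexicons A [normalization_lexicons()].
#' @return Data frame of class `parallel_pairs` with columns `case_id`,
#'   `code`, `source`, `target`.
#' @export
build_pairs <- function(cases, catalog, mode = "curated",
                        lexicons = normalization_lexicons()) {
  stopifnot(inherits(catalog, "code_catalog"), is.data.frame(cases))
  if (!nrow(cases)) {
    out <- data.frame(case_id = character(), code = character(),
                      source = character(), target = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("parallel_pairs", "data.frame")
    return(out)
  }
  code <- pad_code(cases$code)
  idx <- match(code, catalog$entries$code)
  if (anyNA(idx))
    stop("case(s) with code absent from catalog: ",
         paste(cases$case_id[is.na(idx)], collapse = ", "))
  target <- normalize_term(catalog$entries$preferred_term[idx])
  out <- data.frame(case_id = as.character(cases$case_id), code = code,
                    source = build_input(cases, mode, lexicons),
                    target = target, stringsAsFactors = FALSE)
  class(out) <- c("parallel_pairs", "data.frame")
  out
}

# Target-side normalization: lowercase, punctuation to spaces, collapse.
normalize_term <- function(x) {
  normalize_text(x, steps = c("trim", "lowercase"))
}

#' Date-based holdout split
#'
#' Cases dated strictly before the cutoff form the development partition;
#' cases on or after the cutoff form the holdout. The cutoff day itself
#' starts the holdout window. The partition is exhaustive and disjoint.
#'
#' @param cases Data frame with a `date` column (ISO-8601).
#' @param cutoff_date Calendar date starting the holdout period.
#' @return List with `development` and `holdout` data frames.
#' @export
date_split <- function(cases, cutoff_date) {
  stopifnot(is.data.frame(cases))
  d <- as.Date(as.character(cases$date), optional = TRUE)
  if (anyNA(d))
    stop("unparseable date for case(s): ",
         paste(cases$case_id[is.na(d)], collapse = ", "))
  cutoff <- as.Date(cutoff_date)
  list(development = cases[d < cutoff, , drop = FALSE],
       holdout = cases[d >= cutoff, , drop = FALSE])
}

#' Label-stratified train/validation split
#'
#' Splits cases into train and validation sets per label (gold code) so
#' that each label's validation share differs from `val_fraction` by at
#' most one case. Labels with a single case go to train: the model must
#' see every label's target sentence at least once to be able to emit
#' it. Deterministic given the seed.
#'
#' @param cases Data frame with a `code` column.
#' @param val_fraction Validation proportion, strictly in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `validation` data frames.
#' @export
stratified_split <- function(cases, val_fraction = 0.2, seed = 1) {
  stopifnot(is.data.frame(cases))
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("`val_fraction` must be strictly between 0 and 1")
  if (!nrow(cases))
    return(list(train = cases, validation = cases))
  code <- pad_code(cases$code)
  val_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(cases)), code), function(ix) {
      n <- length(ix)
      if (n < 2) return(integer())
      n_val <- round(n * val_fraction)
      if (n_val >= n) n_val <- n - 1L
      if (n_val < 1) return(integer())
      sample(ix, n_val)
    }), use.names = FALSE)
  })
  keep <- setdiff(seq_len(nrow(cases)), val_idx)
  list(train = cases[keep, , drop = FALSE],
       validation = cases[sort(val_idx), , drop = FALSE])
}

#' Write an aligned parallel corpus
#'
#' Serializes pairs as two aligned plain-text files (`<prefix>.src`,
#' `<prefix>.tgt`, one sentence per line) plus a JSON-lines sidecar
#' (`<prefix>.jsonl`) carrying `case_id` and `code`, the layout standard
#' seq2seq tooling consumes.
#'
#' @param pairs A `parallel_pairs` data frame from [build_pairs()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return The prefix path, invisibly.
#' @export
write_parallel_corpus <- function(pairs, dir, prefix = "corpus") {
  stopifnot(inherits(pairs, "parallel_pairs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, prefix)
  writeLines(pairs$source, paste0(base, ".src"))
  writeLines(pairs$target, paste0(base, ".tgt"))
  con <- file(paste0(base, ".jsonl"), "w")
  on.exit(close(con))
  jsonlite::stream_out(pairs[, c("case_id", "code")], con, verbose = FALSE)
  invisible(base)
}

#' Read an aligned parallel corpus written by [write_parallel_corpus()]
#'
#' @param dir Directory holding the corpus files.
#' @param prefix File name prefix.
#' @return A `parallel_pairs` data frame.
#' @export
read_parallel_corpus <- function(dir, prefix = "corpus") {
  base <- file.path(dir, prefix)
  src <- readLines(paste0(base, ".src"), warn = FALSE)
  tgt <- readLines(paste0(base, ".tgt"), warn = FALSE)
  side <- jsonlite::stream_in(file(paste0(base, ".jsonl")), verbose = FALSE)
  stopifnot(length(src) == length(tgt), nrow(side) == length(src))
  out <- data.frame(case_id = side$case_id, code = pad_code(side$code),
                    source = src, target = tgt, stringsAsFactors = FALSE)
  class(out) <- c("parallel_pairs", "data.frame")
  out
}
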