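#' Normalization lexicons
#'
#' Holds the three user-maintained resources of the curation pipeline: a
#' stopword list, a misspelling-to-correction map, and an
#' acronym-to-expansion map. Expansions may be multi-word phrases; a
#' spelling key must not map to itself.
#'
#' @param stopwords Character vector of stopword tokens.
#' @param spelling Named character vector, `names` are misspelled tokens.
#' @param acronyms Named character vector, `names` are acronym tokens.
#' @return Object of class `normalization_lexicons`.
#' @export
normalization_lexicons <- function(stopwords = character(),
                                   spelling = character(),
                                   acronyms = character()) {
  stopwords <- tolower(as.character(stopwords))
  if (length(spelling)) {
    if (is.null(names(spelling)) || any(!nzchar(names(spelling))))
      stop("`spelling` must be a named character vector")
    names(spelling) <- tolower(names(spelling))
    spelling <- tolower(spelling)
    self <- names(spelling) == spelling
    if (any(self))
      stop("spelling key maps to itself: ",
           paste(names(spelling)[self], collapse = ", "))
  }
  if (length(acronyms)) {
    if (is.null(names(acronyms)) || any(!nzchar(names(acronyms))))
      stop("`acronyms` must be a named character vector")
    names(acronyms) <- tolower(names(acronyms))
    acronyms <- tolower(acronyms)
    if (any(!nzchar(trimws(acronyms))))
      stop("acronym expansions must be non-empty")
  }
  structure(list(stopwords = stopwords, spelling = spelling,
                 acronyms = acronyms),
            class = "normalization_lexicons")
}

#' Read a two-column lexicon TSV (key, replacement)
#'
#' @param path Path to a headerless two-column tab-separated file.
#' @return Named character vector.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", quote = "")
  stats::setNames(df[[2]], df[[1]])
}

#' Read a stopword list (one token per line)
#' @param path Path to the stopword file.
#' @return Character vector.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("stopword file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Minimal default English stopword list shipped with the package
#' @return Character vector of function words.
#' @export
default_stopwords <- function() {
  read_stopwords(system.file("extdata", "stopwords.txt",
                             package = "procoder", mustWork = TRUE))
}

# Split on whitespace after stripping punctuation to spaces. The texts
# are short phrases, not prose, so no sentence logic is needed.
tokenize <- function(x) {
  x <- gsub("[^[:alnum:][:space:]]", " ", x)
  x <- collapse_ws(x)
  strsplit(x, " ", fixed = TRUE)
}

# Small rule-based suffix stripper for plural / "-ing" / "-ed" forms,
# with an exception list. Deliberately conservative: 5-token surgical
# phrases do not need a full lemmatizer.
lemma_exceptions <- c("lens", "pancreas", "diabetes", "series", "species",
                      "bypass", "abscess", "pes", "its", "as", "is", "this",
                      "during", "sling", "imaging", "screening", "staged",
                      "closed", "bed")

lemmatize_token <- function(tok) {
  out <- tok
  for (i in seq_along(tok)) {
    t <- tok[i]
    if (t %in% lemma_exceptions || nchar(t) < 4) next
    if (grepl("ies$", t) && nchar(t) > 4) {
      out[i] <- sub("ies$", "y", t)
    } else if (grepl("sses$", t)) {
      out[i] <- sub("sses$", "ss", t)
    } else if (grepl("s$", t) && !grepl("(ss|us|is)$", t)) {
      out[i] <- sub("s$", "", t)
    } else if (grepl("ing$", t) && nchar(t) > 6) {
      out[i] <- sub("ing$", "", t)
    } else if (grepl("ed$", t) && nchar(t) > 5) {
      out[i] <- sub("ed$", "", t)
    }
  }
  out
}

#' Normalize free text
#'
#' Applies the curation pipeline in a fixed order regardless of the order
#' the step flags are given in: trim whitespace, lowercase, expand
#' acronyms, correct misspellings, remove stopwords, lemmatize. Acronym
#' expansion runs before spelling correction so that multi-word
#' expansions are themselves curated. Punctuation is always stripped to
#' spaces by the tokenizer. Deterministic; an empty input yields an
#' empty string.
#'
#' @param text Character vector of raw strings.
#' @param lexicons A [normalization_lexicons()].
#' @param steps Subset of
#'   `c("trim", "lowercase", "acronym", "spell", "stopwords", "lemmatize")`.
#' @return Character vector of single-space-joined normalized tokens
#'   (tokens are recoverable with `strsplit(x, " ")`).
#' @export
normalize_text <- function(text,
                           lexicons = normalization_lexicons(),
                           steps = c("trim", "lowercase", "acronym",
                                     "spell", "stopwords", "lemmatize")) {
  known <- c("trim", "lowercase", "acronym", "spell", "stopwords",
             "lemmatize")
  bad <- setdiff(steps, known)
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
  text <- as.character(text)
  text[is.na(text)] <- ""
  if ("lowercase" %in% steps) text <- tolower(text)
  toks <- tokenize(text)
  vapply(toks, function(tk) {
    if (!length(tk)) return("")
    if ("acronym" %in% steps && length(lexicons$acronyms)) {
      hit <- match(tk, names(lexicons$acronyms))
      expanded <- as.list(tk)
      expanded[!is.na(hit)] <- strsplit(
        unname(lexicons$acronyms[hit[!is.na(hit)]]), " ", fixed = TRUE)
      tk <- unlist(expanded, use.names = FALSE)
    }
    if ("spell" %in% steps && length(lexicons$spelling)) {
      hit <- match(tk, names(lexicons$spelling))
      tk[!is.na(hit)] <- unname(lexicons$spelling[hit[!is.na(hit)]])
    }
    if ("stopwords" %in% steps && length(lexicons$stopwords))
      tk <- tk[!(tk %in% lexicons$stopwords)]
    if ("lemmatize" %in% steps) tk <- lemmatize_token(tk)
    paste(tk, collapse = " ")
  }, character(1))
}

#' Build model input text for an experiment mode
#'
#' Three input modes mirror the experimental settings: `"raw"` passes the
#' procedure text through untouched (experiment 1); `"curated"`
#' normalizes it (experiment 2); `"curated+diagnosis"` appends the
#' normalized preoperative diagnosis to the normalized procedure text
#' (experiment 3). A missing diagnosis in mode 3 degrades to the mode-2
#' input with a warning.
#'
#' @param cases Data frame with `procedure_text` and (for mode 3)
#'   `preop_diagnosis` columns, or a single-case list.
#' @param mode One of `"raw"`, `"curated"`, `"curated+diagnosis"`.
#' @param lexicons A [normalization_lexicons()].
#' @param steps Normalization steps, see [normalize_text()].
#' @return Character vector of source strings, one per case.
#' @export
build_input <- function(cases, mode = c("curated", "raw",
                                        "curated+diagnosis"),
                        lexicons = normalization_lexicons(),
                        steps = c("trim", "lowercase", "acronym", "spell",
                                  "stopwords", "lemmatize")) {
  mode <- match.arg(mode)
  if (!is.data.frame(cases)) cases <- as.data.frame(cases,
                                                    stringsAsFactors = FALSE)
  proc <- as.character(cases$procedure_text)
  if (mode == "raw") return(proc)
  src <- normalize_text(proc, lexicons, steps)
  if (mode == "curated") return(src)
  diag <- as.character(cases$preop_diagnosis %||% rep("", length(proc)))
  diag[is.na(diag)] <- ""
  nd <- normalize_text(diag, lexicons, steps)
  if (any(!nzchar(nd)))
    warning(sum(!nzchar(nd)),
            " case(s) missing a preoperative diagnosis; using the",
            " curated procedure text alone for them")
  collapse_ws(paste(src, nd))
}
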