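#' Construct a validated code catalog
#'
#' A code catalog maps each 5-character procedure code to exactly one
#' canonical description (its preferred term) and a body-region category.
#' The code/term map must be a bijection: duplicate codes or duplicate
#' terms are validation errors.
#'
#' @param code Character vector of code identifiers; padded to 5
#'   characters with leading zeros.
#' @param preferred_term Character vector of canonical descriptions, one
#'   per code, pairwise distinct.
#' @param category Optional character vector of body-region labels. When
#'   `NULL`, categories are derived from `ranges`.
#' @param ranges Data frame of category ranges with columns `category`,
#'   `lo`, `hi` (inclusive code bounds). Defaults to the 19 anesthesiology
#'   body-region ranges, see [body_region_ranges()].
#' @return An object of class `code_catalog`: a list with `entries` (data
#'   frame `code`, `preferred_term`, `category`, in input order) and
#'   `ranges`.
#' @seealso [load_catalog()], [category_of()], [filter_cases()]
#' @export
code_catalog <- function(code, preferred_term, category = NULL,
                         ranges = body_region_ranges()) {
  code <- as.character(code)
  preferred_term <- as.character(preferred_term)
  if (length(code) != length(preferred_term))
    stop("`code` and `preferred_term` must have equal length")
  if (any(is.na(code)) || any(!nzchar(trimws(code))))
    stop("codes must be non-empty")
  code <- pad_code(code)
  if (any(is.na(preferred_term)) || any(!nzchar(trimws(preferred_term))))
    stop("empty preferred term for code(s): ",
         paste(code[!nzchar(trimws(preferred_term))], collapse = ", "))
  dup <- code[duplicated(code)]
  if (length(dup))
    stop("duplicate code(s) in catalog: ", paste(unique(dup), collapse = ", "))
  dup_t <- preferred_term[duplicated(preferred_term)]
  if (length(dup_t))
    stop("duplicate preferred term(s): ",
         paste(unique(dup_t), collapse = "; "))
  ranges <- validate_ranges(ranges)
  if (is.null(category)) {
    category <- range_lookup(code, ranges)
  } else {
    category <- as.character(category)
    if (length(category) != length(code))
      stop("`category` must match `code` in length")
    category[is.na(category) | !nzchar(category)] <- "uncategorized"
  }
  structure(list(
    entries = data.frame(code = code, preferred_term = preferred_term,
                         category = category, stringsAsFactors = FALSE),
    ranges = ranges
  ), class = "code_catalog")
}

validate_ranges <- function(ranges) {
  stopifnot(is.data.frame(ranges),
            all(c("category", "lo", "hi") %in% names(ranges)))
  ranges$lo <- pad_code(ranges$lo)
  ranges$hi <- pad_code(ranges$hi)
  if (any(ranges$lo > ranges$hi)) stop("range lo exceeds hi")
  ord <- order(ranges$lo)
  r <- ranges[ord, ]
  if (nrow(r) > 1 && any(r$lo[-1] <= r$hi[-nrow(r)]))
    stop("category ranges overlap")
  ranges
}

range_lookup <- function(code, ranges) {
  code <- pad_code(code)
  out <- rep("uncategorized", length(code))
  for (i in seq_len(nrow(ranges))) {
    hit <- code >= ranges$lo[i] & code <= ranges$hi[i]
    out[hit] <- ranges$category[i]
  }
  out
}

#' Anesthesiology body-region code ranges
#'
#' The 19 body-region categories used to group anesthesiology procedure
#' codes, as inclusive 5-digit code ranges (head 00100-00222 through
#' "other procedure" 01990-01999).
#'
#' @return Data frame with columns `category`, `lo`, `hi`.
#' @export
body_region_ranges <- function() {
  data.frame(
    category = c(
      "Head", "Neck", "Thorax (chest and shoulder)", "Intrathoracic",
      "Spine and spinal cord", "Upper abdomen", "Lower abdomen", "Perineum",
      "Pelvis (except hip)", "Upper leg (except knee)",
      "Knee and popliteal area", "Lower leg (below knee)",
      "Shoulder and axilla", "Upper arm and elbow",
      "Forearm, wrist, and hand", "Radiological procedure",
      "Burn excisions or debridement", "Obstetric", "Other procedure"),
    lo = c("00100", "00300", "00400", "00500", "00600", "00700", "00800",
           "00902", "01112", "01200", "01320", "01462", "01610", "01710",
           "01810", "01916", "01951", "01958", "01990"),
    hi = c("00222", "00352", "00474", "00580", "00670", "00797", "00882",
           "00952", "01173", "01274", "01444", "01522", "01680", "01782",
           "01860", "01936", "01953", "01969", "01999"),
    stringsAsFactors = FALSE
  )
}

#' Body-region category of a code
#'
#' Returns the category label of the unique range containing each code,
#' or `"uncategorized"` for codes outside every range. Containment uses
#' string comparison on zero-padded 5-character forms, equivalent to
#' numeric comparison for 5-digit codes.
#'
#' @param catalog A [code_catalog()].
#' @param code Character vector of codes.
#' @return Character vector of category labels.
#' @export
category_of <- function(catalog, code) {
  stopifnot(inherits(catalog, "code_catalog"))
  range_lookup(code, catalog$ranges)
}

#' Look up preferred terms for codes
#'
#' @param catalog A [code_catalog()].
#' @param code Character vector of codes present in the catalog.
#' @return Character vector of preferred terms.
#' @export
lookup_term <- function(catalog, code) {
  stopifnot(inherits(catalog, "code_catalog"))
  idx <- match(pad_code(code), catalog$entries$code)
  if (anyNA(idx))
    stop("code(s) not in catalog: ",
         paste(pad_code(code)[is.na(idx)], collapse = ", "))
  catalog$entries$preferred_term[idx]
}

#' Read a code catalog from a TSV file
#'
#' The file must be tab-separated with a header row and columns `code`,
#' `preferred_term`, and optionally `category`. Entry order is file
#' order.
#'
#' @param path Path to the catalog TSV.
#' @param ranges Category ranges passed to [code_catalog()].
#' @return A validated [code_catalog()].
#' @export
load_catalog <- function(path, ranges = body_region_ranges()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("code", "preferred_term")
  if (!all(need %in% names(df)))
    stop("catalog file must have columns: ", paste(need, collapse = ", "))
  code_catalog(df$code, df$preferred_term,
               category = if ("category" %in% names(df)) df$category else NULL,
               ranges = ranges)
}

#' Write a code catalog to a TSV file
#'
#' Inverse of [load_catalog()]: writing then reloading yields an
#' identical catalog.
#'
#' @param catalog A [code_catalog()].
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "code_catalog"))
  write.table(catalog$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Filter a case table against a catalog
#'
#' Excludes cases whose code is absent from the catalog (invalid) or
#' listed as deprecated, mirroring the data-selection flow of registry
#' curation. Nothing is raised: all exclusions are reported.
#'
#' @param cases Data frame with at least a `code` column.
#' @param catalog A [code_catalog()].
#' @param deprecated Character vector of deprecated codes. The default
#'   holds the two upper/lower gastrointestinal anesthesia codes retired
#'   in 2018 (00740, 00810).
#' @return List with `cases` (retained rows) and `report`, a
#'   `case_filter_report` whose counts reconcile with the input
#'   (`retained + excluded_invalid + excluded_deprecated == nrow(cases)`).
#' @export
filter_cases <- function(cases, catalog,
                         deprecated = c("00740", "00810")) {
  stopifnot(inherits(catalog, "code_catalog"), is.data.frame(cases),
            "code" %in% names(cases))
  code <- pad_code(cases$code)
  deprecated <- pad_code(deprecated)
  is_dep <- code %in% deprecated
  is_inv <- !is_dep & !(code %in% catalog$entries$code)
  keep <- !is_dep & !is_inv
  excluded <- data.frame(
    code = code[!keep],
    reason = ifelse(is_dep[!keep], "deprecated", "invalid"),
    stringsAsFactors = FALSE)
  report <- structure(list(
    retained = sum(keep),
    excluded_invalid = sum(is_inv),
    excluded_deprecated = sum(is_dep),
    excluded_codes = excluded
  ), class = "case_filter_report")
  list(cases = cases[keep, , drop = FALSE], report = report)
}

#' @export
print.case_filter_report <- function(x, ...) {
  cat("Case filter report\n")
  cat("  retained:           ", x$retained, "\n")
  cat("  excluded invalid:   ", x$excluded_invalid, "\n")
  cat("  excluded deprecated:", x$excluded_deprecated, "\n")
  invisible(x)
}

#' @export
print.code_catalog <- function(x, ...) {
  cat("Code catalog:", nrow(x$entries), "codes,",
      length(unique(x$entries$category)), "categories\n")
  print(head(x$entries, 5))
  if (nrow(x$entries) > 5) cat("  ...\n")
  invisible(x)
}

#' Read a case table from TSV or JSON-lines
#'
#' Cases carry `case_id`, `date` (ISO-8601), `procedure_text`,
#' `preop_diagnosis` and `code`.
#'
#' @param path Path to a `.tsv` or `.jsonl` file.
#' @return Data frame of cases.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path)
  if (grepl("\\.jsonl?$", path)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- read.delim(path, sep = "\t", colClasses = "character",
                     stringsAsFactors = FALSE, quote = "")
  }
  need <- c("case_id", "date", "procedure_text", "preop_diagnosis", "code")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("case table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$code <- pad_code(df$code)
  df
}

#' Write a case table
#'
#' @param cases Data frame of cases.
#' @param path Output path; `.jsonl` writes JSON-lines, anything else TSV.
#' @export
write_cases <- function(cases, path) {
  if (grepl("\\.jsonl?$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    jsonlite::stream_out(cases, con, verbose = FALSE)
  } else {
    write.table(cases, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
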