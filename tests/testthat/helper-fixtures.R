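# Shared fixtures, built in code at test time.

# A tiny hand-built catalog with codes drawn from real body-region ranges.
toy_catalog <- function() {
  code_catalog(
    code = c("00104", "00142", "00868", "01402"),
    preferred_term = c(
      "Anesthesia for electroconvulsive therapy",
      "Anesthesia for procedures on eye; lens surgery",
      paste("Anesthesia for extraperitoneal procedures in lower abdomen,",
            "including urinary tract; renal transplant (recipient)"),
      paste("Anesthesia for open or surgical arthroscopic procedures on",
            "knee joint; total knee arthroplasty")))
}

toy_cases <- function() {
  data.frame(
    case_id = c("c1", "c2", "c3", "c4"),
    date = c("2017-03-01", "2018-06-15", "2019-01-01", "2019-04-02"),
    procedure_text = c("Electroconvulsive therapy",
                       "Left phacoemulsification intraocular lens",
                       "Right kidney transplant cadaveric donor",
                       "Right total knee arthroplasty"),
    preop_diagnosis = c("depression", "cataract", "renal failure",
                        "knee arthritis"),
    code = c("00104", "00142", "00868", "01402"),
    stringsAsFactors = FALSE)
}

# Definitional Levenshtein: plain recursion on the edit recurrence,
# memoized only to make exhaustion feasible. Independent of the C++ DP.
lev_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# All strings of length <= n over the given alphabet.
all_strings <- function(n, alphabet = c("a", "b")) {
  out <- ""
  for (len in seq_len(n)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Memoized scaled-down experiment pipeline (50 codes, ~2000 development
# cases, moderate noise) shared by the end-to-end tests so the
# translation model is trained once per mode.
.pipeline_cache <- new.env(parent = emptyenv())

pipeline_fixture <- function(mode = "curated") {
  key <- paste0("mode_", mode)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  if (is.null(.pipeline_cache$base)) {
    catalog <- make_catalog(50, seed = 101)
    cfg <- synth_config(n_codes = 50, n_cases = 2400, seed = 101)
    sim <- simulate_cases(catalog, cfg)
    lex <- synth_lexicons(catalog)
    sp <- date_split(sim$cases, "2019-02-01")
    .pipeline_cache$base <- list(catalog = catalog, sim = sim, lex = lex,
                                 development = sp$development,
                                 holdout = sp$holdout)
  }
  base <- .pipeline_cache$base
  pairs <- build_pairs(base$development, base$catalog, mode = mode,
                       lexicons = base$lex)
  hold <- build_pairs(base$holdout, base$catalog, mode = mode,
                      lexicons = base$lex)
  model <- nmt_train(pairs, nmt_config(seed = 101))
  cands <- translate(model, hold$source, k = 3)
  preds <- predict_codes(score_matrix(cands, base$catalog,
                                      metric = "mean"),
                         ids = hold$case_id)
  res <- c(base, list(pairs = pairs, hold = hold, model = model,
                      cands = cands, preds = preds, mode = mode))
  .pipeline_cache[[key]] <- res
  res
}
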