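# Synthetic catalogs and operative-case corpora with the statistical
# structure of a perioperative registry: long canonical descriptions
# (mean ~13 tokens), short noisy procedure texts (mean ~5 tokens),
# shorter informative diagnoses (mean ~4 tokens), and a long-tailed
# Zipf label law (top ~20% of codes carrying ~80% of cases).

synth_proc_types <- function() {
  data.frame(
    full = c("open repair", "endoscopic exploration", "radical resection",
             "percutaneous drainage", "diagnostic biopsy",
             "total replacement", "closed reduction", "wide excision",
             "laparoscopic removal", "reconstructive revision",
             "microsurgical decompression", "guided aspiration",
             "primary fusion", "staged debridement"),
    short = c("repair", "endoscopic", "resection", "drainage", "biopsy",
              "replacement", "reduction", "excision", "removal",
              "revision", "decompression", "aspiration", "fusion",
              "debridement"),
    dx = c("defect", "stricture", "neoplasm", "abscess", "lesion",
           "degeneration", "fracture", "tumor", "calculus", "malunion",
           "stenosis", "effusion", "instability", "necrosis"),
    stringsAsFactors = FALSE)
}

synth_anatomy <- function() {
  list(
    "Head" = c("cranial vault", "scalp", "skull base"),
    "Neck" = c("cervical trachea", "thyroid bed", "carotid sheath"),
    "Thorax (chest and shoulder)" = c("chest wall", "sternum",
                                      "pectoral girdle"),
    "Intrathoracic" = c("pleural cavity", "mediastinum",
                        "pulmonary hilum"),
    "Spine and spinal cord" = c("lumbar spine", "thoracic spine",
                                "spinal canal"),
    "Upper abdomen" = c("gastric antrum", "hepatic lobe", "biliary tree"),
    "Lower abdomen" = c("pelvic colon", "urinary bladder",
                        "inguinal canal"),
    "Perineum" = c("perineal body", "anal canal", "urethral meatus"),
    "Pelvis (except hip)" = c("iliac crest", "pubic ramus",
                              "sacroiliac joint"),
    "Upper leg (except knee)" = c("femoral shaft", "proximal femur",
                                  "gluteal compartment"),
    "Knee and popliteal area" = c("knee joint", "patellar tendon",
                                  "popliteal fossa"),
    "Lower leg (below knee)" = c("tibial plateau", "ankle mortise",
                                 "calcaneal tuberosity"),
    "Shoulder and axilla" = c("rotator cuff", "axillary fold",
                              "glenohumeral joint"),
    "Upper arm and elbow" = c("humeral shaft", "olecranon process",
                              "antecubital fossa"),
    "Forearm, wrist, and hand" = c("carpal tunnel", "radial styloid",
                                   "palmar fascia"),
    "Radiological procedure" = c("vascular access", "imaging field",
                                 "interventional site"),
    "Burn excisions or debridement" = c("burn eschar", "grafted dermis",
                                        "debrided wound"),
    "Obstetric" = c("gravid uterus", "birth canal", "placental bed"),
    "Other procedure" = c("unlisted site", "ancillary site",
                          "special site"))
}

synth_extras <- function() {
  data.frame(
    clause = c("including adjacent lymphatic structures",
               "including regional vascular control",
               "involving the deep fascial planes",
               "with prosthetic device placement",
               "with intraoperative image guidance",
               "with autologous graft harvesting",
               "performed for malignancy",
               "performed for acute trauma",
               "requiring staged closure",
               "not otherwise specified"),
    keyword = c("lymphatic", "vascular", "fascial", "prosthetic",
                "image", "graft", "malignancy", "trauma", "staged",
                "specified"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic code catalog
#'
#' Builds `n_codes` codes spread over the 19 body-region ranges, each
#' with a pairwise-distinct template-generated preferred term (mean
#' around 13 tokens, mimicking controlled-vocabulary descriptions), a
#' distinct canonical short phrase (3-7 tokens, the "what a surgeon
#' would type" compression of the term, built from the term's own
#' content words), a small per-code diagnosis vocabulary that is
#' informative about the code, and an acronym table derived from the
#' first letters of multiword anatomy phrases. Deterministic given
#' `seed`.
#'
#' @param n_codes Number of codes (at least 2).
#' @param seed Integer seed.
#' @return A [code_catalog()] whose `"synth"` attribute carries the
#'   short phrases, the acronym table and the diagnosis vocabulary used
#'   by [simulate_cases()].
#' @export
make_catalog <- function(n_codes, seed = 1) {
  stopifnot(n_codes >= 2)
  proc <- synth_proc_types()
  anat <- synth_anatomy()
  extras <- synth_extras()
  anat_df <- data.frame(
    category = rep(names(anat), lengths(anat)),
    anatomy = unlist(anat, use.names = FALSE), stringsAsFactors = FALSE)
  combos <- expand.grid(a = seq_len(nrow(anat_df)),
                        p = seq_len(nrow(proc)))
  if (n_codes > nrow(combos))
    stop("n_codes exceeds the ", nrow(combos),
         " distinct anatomy-procedure combinations available")
  ranges <- body_region_ranges()
  capacity <- stats::setNames(
    as.integer(ranges$hi) - as.integer(ranges$lo) + 1L, ranges$category)
  with_seed(stream_seed(seed, "catalog"), {
    # accept shuffled anatomy-procedure combos while each category still
    # has free codes in its range
    shuffled <- combos[sample.int(nrow(combos)), ]
    used <- stats::setNames(integer(length(capacity)), names(capacity))
    take <- logical(nrow(shuffled))
    for (i in seq_len(nrow(shuffled))) {
      cc <- anat_df$category[shuffled$a[i]]
      if (used[cc] < capacity[cc]) {
        used[cc] <- used[cc] + 1L
        take[i] <- TRUE
        if (sum(take) == n_codes) break
      }
    }
    if (sum(take) < n_codes)
      stop("cannot place ", n_codes, " codes within the category ranges")
    pick <- shuffled[take, ]
    cat_of <- anat_df$category[pick$a]
    # sequential codes within each category's range
    code <- character(n_codes)
    for (cc in unique(cat_of)) {
      ix <- which(cat_of == cc)
      lo <- as.integer(ranges$lo[ranges$category == cc])
      code[ix] <- pad_code(lo + seq_along(ix) - 1L)
    }
    term <- character(n_codes)
    phrase <- character(n_codes)
    acronyms <- character(0)
    dx_vocab <- vector("list", n_codes)
    severities <- c("chronic", "acute", "recurrent", "progressive",
                    "symptomatic")
    for (i in seq_len(n_codes)) {
      an <- anat_df$anatomy[pick$a[i]]
      pr <- proc$full[pick$p[i]]
      n_extra <- sample(0:3, 1, prob = c(0.25, 0.40, 0.25, 0.10))
      ex <- if (n_extra) extras[sample.int(nrow(extras), n_extra), ,
                                drop = FALSE] else extras[0, ]
      term[i] <- paste(c(sprintf("anesthesia for %s procedures on the %s",
                                 pr, an), ex$clause), collapse = " ")
      # canonical short phrase: a compression of the term built from its
      # own content words (anatomy, procedure shorthand, one keyword per
      # qualifier clause) plus an optional laterality decoration, so the
      # phrase-to-term token overlap grows with term length
      an_tok <- strsplit(an, " ", fixed = TRUE)[[1]]
      tk <- c(an_tok, proc$short[pick$p[i]], ex$keyword)
      if (length(tk) < 3 || stats::runif(1) < 0.5)
        tk <- c(sample(c("left", "right", "bilateral"), 1), tk)
      phrase[i] <- paste(tk, collapse = " ")
      # informative diagnoses: anatomy word + procedure-linked disease
      dxn <- proc$dx[pick$p[i]]
      dx_vocab[[i]] <- vapply(seq_len(3), function(j) {
        sev <- sample(severities, 1)
        base <- c(sev, an_tok[1], dxn)
        if (stats::runif(1) < 0.4)
          base <- c(base, sample(c("requiring surgery", "with pain",
                                   "refractory"), 1))
        collapse_ws(paste(base, collapse = " "))
      }, character(1))
    }
    # acronym table: first letters of multiword anatomy phrases
    multi <- unique(anat_df$anatomy[vapply(strsplit(anat_df$anatomy, " "),
                                           length, integer(1)) > 1])
    acr <- vapply(strsplit(multi, " ", fixed = TRUE),
                  function(w) paste(substr(w, 1, 1), collapse = ""),
                  character(1))
    keep <- !duplicated(acr)
    acronyms <- stats::setNames(multi[keep], acr[keep])
    ord <- order(code)
    catalog <- code_catalog(code[ord], term[ord])
    attr(catalog, "synth") <- list(
      phrase = phrase[ord], acronyms = acronyms,
      dx_vocab = dx_vocab[ord], seed = seed)
    catalog
  })
}

#' Configuration for the synthetic case generator
#'
#' Noise rates and corpus shape. The defaults are the emulated registry
#' conditions: 20,000 cases over 250 codes, Zipf exponent 1.2 (the top
#' 20% of codes carry roughly 80% of cases), per-token misspelling and
#' dropout rates of 0.1, and service dates spanning 2.5 years so that a
#' date cutoff can carve out a future holdout window.
#'
#' @param n_codes,n_cases Corpus dimensions (`n_cases >= n_codes`).
#' @param zipf_exponent Positive exponent of the label frequency law.
#' @param misspell_rate Per-token probability of a random character edit.
#' @param acronym_rate Per-case probability of compressing a multiword
#'   anatomy phrase to its acronym.
#' @param token_dropout_rate Per-token deletion probability (at least
#'   one token always survives).
#' @param reorder_rate Per-case probability of swapping one adjacent
#'   token pair.
#' @param diagnosis_vocab_per_code Diagnosis phrases per code.
#' @param date_range Character vector of two ISO dates.
#' @param seed Integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_codes = 250, n_cases = 20000,
                         zipf_exponent = 1.2, misspell_rate = 0.1,
                         acronym_rate = 0.15, token_dropout_rate = 0.1,
                         reorder_rate = 0.05,
                         diagnosis_vocab_per_code = 3,
                         date_range = c("2017-01-01", "2019-06-30"),
                         seed = 1) {
  rates <- c(misspell_rate, acronym_rate, token_dropout_rate,
             reorder_rate)
  if (any(rates < 0 | rates > 1))
    stop("noise rates must lie in [0, 1]")
  stopifnot(n_codes >= 2, n_cases >= n_codes, zipf_exponent > 0)
  structure(list(n_codes = as.integer(n_codes),
                 n_cases = as.integer(n_cases),
                 zipf_exponent = zipf_exponent,
                 misspell_rate = misspell_rate,
                 acronym_rate = acronym_rate,
                 token_dropout_rate = token_dropout_rate,
                 reorder_rate = reorder_rate,
                 diagnosis_vocab_per_code =
                   as.integer(diagnosis_vocab_per_code),
                 date_range = as.character(date_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Largest-remainder apportionment of n cases to Zipf-law ranks;
# remainders tie-break toward the lower rank, so counts are monotone
# non-increasing in rank.
zipf_counts <- function(n_cases, n_codes, s) {
  p <- (seq_len(n_codes))^(-s)
  p <- p / sum(p)
  target <- n_cases * p
  base <- floor(target)
  rem <- n_cases - sum(base)
  if (rem > 0) {
    ord <- order(-(target - base), seq_len(n_codes))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

random_misspell <- function(tok) {
  letters_pool <- letters
  type <- sample(c("sub", "ins", "del"), 1)
  n <- nchar(tok)
  if (n <= 1 && type == "del") type <- "ins"
  out <- tok
  if (type == "sub") {
    i <- sample.int(n, 1)
    ch <- sample(letters_pool, 1)
    substr(out, i, i) <- ch
  } else if (type == "ins") {
    i <- sample.int(n + 1, 1)
    out <- paste0(substr(tok, 1, i - 1), sample(letters_pool, 1),
                  substr(tok, i, n))
  } else {
    i <- sample.int(n, 1)
    out <- paste0(substr(tok, 1, i - 1), substr(tok, i + 1, n))
  }
  if (identical(out, tok) || !nzchar(out)) tok else out
}

apply_op <- function(tokens, op) {
  switch(op$type,
    acronym = {
      after <- if (op$pos + op$len <= length(tokens))
        tokens[(op$pos + op$len):length(tokens)] else character(0)
      c(head(tokens, op$pos - 1), op$to, after)
    },
    misspell = { tokens[op$pos] <- op$to; tokens },
    dropout = tokens[-op$pos],
    swap = { tmp <- tokens[op$pos]
             tokens[op$pos] <- tokens[op$pos + 1]
             tokens[op$pos + 1] <- tmp
             tokens },
    stop("unknown operator: ", op$type))
}

#' Simulate operative cases from a synthetic catalog
#'
#' Draws each case's gold code from a truncated Zipf law over the
#' catalog (largest-remainder apportionment, so the emitted label
#' histogram is exactly non-increasing in designed rank), derives its
#' procedure text from the code's canonical short phrase, and corrupts
#' it with the configured noise operators in a fixed order: acronym
#' compression, per-token character-edit misspelling, token dropout
#' (never below one token), adjacent-token reordering. Every applied
#' operator is recorded so the emitted text can be replayed exactly
#' from the canonical phrase. The preoperative diagnosis is drawn from
#' the code's own diagnosis vocabulary (informative about the code);
#' service dates are uniform over `date_range`. Fully deterministic
#' given `config$seed`.
#'
#' @param catalog A catalog from [make_catalog()].
#' @param config A [synth_config()]; its `n_codes` must match the
#'   catalog.
#' @return List with `cases` (data frame `case_id`, `date`,
#'   `procedure_text`, `preop_diagnosis`, `code`) and `truth`, a
#'   `synth_truth` object recording canonical phrases and operator
#'   sequences (see [replay_truth()]).
#' @export
simulate_cases <- function(catalog, config = synth_config()) {
  stopifnot(inherits(catalog, "code_catalog"),
            inherits(config, "synth_config"))
  synth <- attr(catalog, "synth")
  if (is.null(synth))
    stop("`catalog` must come from make_catalog()")
  n_codes <- nrow(catalog$entries)
  if (config$n_codes != n_codes)
    stop("config$n_codes (", config$n_codes,
         ") does not match the catalog (", n_codes, ")")
  seed <- config$seed
  counts <- zipf_counts(config$n_cases, n_codes, config$zipf_exponent)
  # rank 1 = most frequent; map ranks onto catalog rows deterministically
  rank_of_row <- with_seed(stream_seed(seed, "labels"),
                           sample.int(n_codes))
  row_of_rank <- order(rank_of_row)
  label_rows <- rep(row_of_rank, times = counts)
  case_order <- with_seed(stream_seed(seed, "order"),
                          sample.int(length(label_rows)))
  label_rows <- label_rows[case_order]
  n <- length(label_rows)
  acr_table <- synth$acronyms
  acr_of_phrase <- stats::setNames(names(acr_table), acr_table)
  out_text <- character(n)
  ops_all <- vector("list", n)
  with_seed(stream_seed(seed, "noise"), {
    for (i in seq_len(n)) {
      row <- label_rows[i]
      tokens <- strsplit(synth$phrase[row], " ", fixed = TRUE)[[1]]
      ops <- list()
      if (config$acronym_rate > 0 && stats::runif(1) < config$acronym_rate) {
        # find a multiword anatomy phrase inside the token stream
        for (ph in names(acr_of_phrase)) {
          pw <- strsplit(ph, " ", fixed = TRUE)[[1]]
          L <- length(pw)
          if (L < 2 || length(tokens) < L) next
          hit <- which(vapply(seq_len(length(tokens) - L + 1), function(p)
            all(tokens[p:(p + L - 1)] == pw), logical(1)))
          if (length(hit)) {
            op <- list(type = "acronym", pos = hit[1], len = L,
                       to = unname(acr_of_phrase[ph]))
            tokens <- apply_op(tokens, op)
            ops[[length(ops) + 1]] <- op
            break
          }
        }
      }
      if (config$misspell_rate > 0) {
        for (p in seq_along(tokens)) {
          if (stats::runif(1) < config$misspell_rate) {
            op <- list(type = "misspell", pos = p,
                       to = random_misspell(tokens[p]))
            tokens <- apply_op(tokens, op)
            ops[[length(ops) + 1]] <- op
          }
        }
      }
      if (config$token_dropout_rate > 0) {
        p <- 1L
        while (p <= length(tokens)) {
          if (length(tokens) > 1 &&
              stats::runif(1) < config$token_dropout_rate) {
            op <- list(type = "dropout", pos = p)
            tokens <- apply_op(tokens, op)
            ops[[length(ops) + 1]] <- op
          } else {
            p <- p + 1L
          }
        }
      }
      if (config$reorder_rate > 0 && length(tokens) >= 2 &&
          stats::runif(1) < config$reorder_rate) {
        op <- list(type = "swap",
                   pos = sample.int(length(tokens) - 1L, 1))
        tokens <- apply_op(tokens, op)
        ops[[length(ops) + 1]] <- op
      }
      out_text[i] <- paste(tokens, collapse = " ")
      ops_all[[i]] <- ops
    }
  })
  diagnosis <- with_seed(stream_seed(seed, "diagnosis"), {
    vapply(label_rows, function(row) {
      v <- synth$dx_vocab[[row]]
      v[sample.int(length(v), 1)]
    }, character(1))
  })
  dates <- with_seed(stream_seed(seed, "dates"), {
    d0 <- as.Date(config$date_range[1])
    d1 <- as.Date(config$date_range[2])
    format(d0 + sample.int(as.integer(d1 - d0) + 1L, n,
                           replace = TRUE) - 1L)
  })
  cases <- data.frame(
    case_id = sprintf("case%06d", seq_len(n)),
    date = dates,
    procedure_text = out_text,
    preop_diagnosis = diagnosis,
    code = catalog$entries$code[label_rows],
    stringsAsFactors = FALSE)
  truth <- structure(list(
    canonical = synth$phrase[label_rows],
    code = catalog$entries$code[label_rows],
    ops = ops_all), class = "synth_truth")
  list(cases = cases, truth = truth)
}

#' Replay recorded noise operators
#'
#' Applies each case's recorded operator sequence to its canonical
#' phrase; the result reproduces the emitted `procedure_text` exactly.
#'
#' @param truth A `synth_truth` from [simulate_cases()].
#' @return Character vector of reconstructed procedure texts.
#' @export
replay_truth <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  vapply(seq_along(truth$canonical), function(i) {
    tokens <- strsplit(truth$canonical[i], " ", fixed = TRUE)[[1]]
    for (op in truth$ops[[i]]) tokens <- apply_op(tokens, op)
    paste(tokens, collapse = " ")
  }, character(1))
}

#' Lexicons matching a synthetic catalog
#'
#' The acronym table emitted by [make_catalog()] as a
#' [normalization_lexicons()] object (with the packaged default
#' stopword list), so the curation pipeline can be exercised end to end
#' on synthetic corpora.
#'
#' @param catalog A catalog from [make_catalog()].
#' @param stopwords Stopword list; defaults to [default_stopwords()].
#' @return A [normalization_lexicons()].
#' @export
synth_lexicons <- function(catalog, stopwords = default_stopwords()) {
  synth <- attr(catalog, "synth")
  if (is.null(synth)) stop("`catalog` must come from make_catalog()")
  normalization_lexicons(stopwords = stopwords,
                         acronyms = synth$acronyms)
}

#' Write a synthetic corpus to disk
#'
#' Emits the catalog TSV, cases as JSON-lines, the acronym lexicon TSV,
#' the stopword list, and the truth record as JSON-lines.
#'
#' @param catalog A catalog from [make_catalog()].
#' @param sim A [simulate_cases()] result.
#' @param dir Output directory.
#' @export
write_synth_corpus <- function(catalog, sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_catalog(catalog, file.path(dir, "catalog.tsv"))
  write_cases(sim$cases, file.path(dir, "cases.jsonl"))
  synth <- attr(catalog, "synth")
  acr <- synth$acronyms
  writeLines(paste(names(acr), unname(acr), sep = "\t"),
             file.path(dir, "acronyms.tsv"))
  writeLines(default_stopwords(), file.path(dir, "stopwords.txt"))
  truth_df <- data.frame(
    canonical = sim$truth$canonical, code = sim$truth$code,
    ops = vapply(sim$truth$ops, function(o)
      jsonlite::toJSON(o, auto_unbox = TRUE), character(1)),
    stringsAsFactors = FALSE)
  con <- file(file.path(dir, "truth.jsonl"), "w")
  on.exit(close(con))
  jsonlite::stream_out(truth_df, con, verbose = FALSE)
  invisible(dir)
}
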