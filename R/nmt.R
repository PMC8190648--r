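#' Configuration for the translation model
#'
#' Desk-scale defaults for the encoder-decoder Transformer used in the
#' translation step: 2 encoder and 2 decoder layers, 64-dimensional
#' embeddings, 4 attention heads, a 128-unit feed-forward block,
#' word-level vocabulary and beam width 5. The method does not depend on
#' model size; these defaults train in minutes on one CPU.
#'
#' @param embed_dim Embedding/model width (positive, divisible by
#'   `heads`).
#' @param layers Encoder and decoder layer count.
#' @param heads Attention heads.
#' @param ffn_dim Feed-forward inner width.
#' @param max_len Maximum sequence length (source, and target + BOS).
#' @param beam_size Beam width; must be at least the number of candidate
#'   translations later requested (>= 3 by default use).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param label_smoothing Cross-entropy label-smoothing mass.
#' @param grad_clip Global gradient-norm clip (0 disables).
#' @param seed Integer seed; training and decoding are deterministic
#'   given the seed.
#' @return Object of class `nmt_config`.
#' @export
nmt_config <- function(embed_dim = 64, layers = 2, heads = 4,
                       ffn_dim = 128, max_len = 40, beam_size = 5,
                       epochs = 20, lr = 1e-3, label_smoothing = 0.1,
                       grad_clip = 1.0, seed = 1) {
  stopifnot(embed_dim >= 1, layers >= 1, heads >= 1, ffn_dim >= 1,
            max_len >= 2, beam_size >= 1, epochs >= 1, lr > 0)
  if (embed_dim %% heads != 0)
    stop("`embed_dim` must be divisible by `heads`")
  structure(list(embed_dim = as.integer(embed_dim),
                 layers = as.integer(layers), heads = as.integer(heads),
                 ffn_dim = as.integer(ffn_dim),
                 max_len = as.integer(max_len),
                 beam_size = as.integer(beam_size),
                 epochs = as.integer(epochs), lr = lr,
                 label_smoothing = label_smoothing,
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "nmt_config")
}

# Word-level vocabulary over both corpus sides. Ids are 0-based for the
# C++ core: 0 = <unk>, 1 = <bos>, 2 = <eos>, words from 3. Unknown
# source tokens at decode time map to <unk>.
build_vocab <- function(pairs) {
  words <- sort(unique(unlist(strsplit(c(pairs$source, pairs$target), " ",
                                       fixed = TRUE))))
  words[nzchar(words)]
}

encode_ids <- function(texts, vocab) {
  toks <- strsplit(texts, " ", fixed = TRUE)
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    id <- match(tk, vocab)
    as.integer(ifelse(is.na(id), 0L, id + 2L))
  })
}

decode_ids <- function(ids, vocab) {
  vapply(ids, function(v) {
    w <- ifelse(v >= 3L, vocab[v - 2L], "<unk>")
    paste(w, collapse = " ")
  }, character(1))
}

#' Train the translation model
#'
#' Fits the Transformer on source/target sentence pairs with teacher
#' forcing, label-smoothed cross-entropy and Adam, one sequence per
#' update. Training is deterministic given `config$seed`.
#'
#' @param pairs A `parallel_pairs` data frame from [build_pairs()] (or
#'   any data frame with `source` and `target` character columns).
#' @param config An [nmt_config()].
#' @param verbose Print per-epoch loss.
#' @return Object of class `nmt_model`: flattened parameters, the
#'   vocabulary, the configuration, and the per-epoch training loss.
#' @export
nmt_train <- function(pairs, config = nmt_config(), verbose = FALSE) {
  stopifnot(inherits(config, "nmt_config"), is.data.frame(pairs))
  if (!nrow(pairs)) stop("cannot train on an empty pair collection")
  vocab <- build_vocab(pairs)
  src <- encode_ids(pairs$source, vocab)
  tgt <- encode_ids(pairs$target, vocab)
  too_long <- which(lengths(tgt) + 1L > config$max_len |
                      lengths(src) > config$max_len)
  if (length(too_long)) {
    id <- if ("case_id" %in% names(pairs))
      pairs$case_id[too_long] else too_long
    stop("max_len (", config$max_len, ") exceeded by pair(s): ",
         paste(head(id, 5), collapse = ", "))
  }
  if (any(lengths(src) == 0))
    stop("empty source sentence(s) in training pairs")
  fit <- cpp_nmt_train(src, tgt, length(vocab) + 3L, config$embed_dim,
                       config$heads, config$layers, config$ffn_dim,
                       config$max_len, config$epochs, config$lr,
                       config$label_smoothing, config$grad_clip,
                       config$seed, verbose)
  structure(list(params = fit$params, vocab = vocab, config = config,
                 loss = as.numeric(fit$loss)),
            class = "nmt_model")
}

#' @export
print.nmt_model <- function(x, ...) {
  cat("Transformer translation model\n")
  cat("  vocab:", length(x$vocab), "words;",
      format(length(x$params), big.mark = ","), "parameters\n")
  cat("  layers:", x$config$layers, "+", x$config$layers,
      " embed:", x$config$embed_dim, " heads:", x$config$heads, "\n")
  cat("  final training loss:", round(tail(x$loss, 1), 4), "\n")
  invisible(x)
}

#' Translate sources into ranked candidate descriptions
#'
#' Beam-search decodes each source and returns the `k` highest-scoring
#' distinct hypotheses, best first. Scores are length-normalized
#' log-probabilities, non-increasing in rank. Hypotheses that stringify
#' identically after detokenization are deduplicated, keeping the best
#' score.
#'
#' @param model An [nmt_train()] fit.
#' @param source Character vector of source sentences (non-empty).
#' @param k Number of candidates to retain (the transformation step uses
#'   the top three); must not exceed `config$beam_size`.
#' @return List of `translation_candidates` objects, one per source:
#'   each has `source` and a data frame `candidates` with `sentence` and
#'   `score`.
#' @export
translate <- function(model, source, k = 3) {
  stopifnot(inherits(model, "nmt_model"))
  if (k < 1) stop("`k` must be at least 1")
  if (k > model$config$beam_size)
    stop("`k` (", k, ") exceeds beam_size (", model$config$beam_size, ")")
  source <- as.character(source)
  if (any(is.na(source) | !nzchar(trimws(source))))
    stop("empty source sentence(s) at position(s): ",
         paste(which(is.na(source) | !nzchar(trimws(source))),
               collapse = ", "))
  cfg <- model$config
  ids <- encode_ids(source, model$vocab)
  ids <- lapply(ids, function(v) head(v, cfg$max_len))
  raw <- cpp_nmt_decode(model$params, ids, length(model$vocab) + 3L,
                        cfg$embed_dim, cfg$heads, cfg$layers, cfg$ffn_dim,
                        cfg$max_len, cfg$beam_size, as.integer(k))
  out <- lapply(seq_along(raw), function(i) {
    sent <- decode_ids(raw[[i]]$tokens, model$vocab)
    score <- raw[[i]]$scores
    keep <- nzchar(sent)
    sent <- sent[keep]; score <- score[keep]
    if (!length(sent)) { sent <- "<unk>"; score <- -Inf }
    first <- !duplicated(sent)
    sent <- sent[first]; score <- score[first]
    ord <- order(-score)
    take <- head(ord, k)
    structure(list(source = source[i],
                   candidates = data.frame(sentence = sent[take],
                                           score = score[take],
                                           stringsAsFactors = FALSE),
                   k = as.integer(k)),
              class = "translation_candidates")
  })
  names(out) <- names(source)
  out
}

#' @export
print.translation_candidates <- function(x, ...) {
  cat("source:", x$source, "\n")
  for (i in seq_len(nrow(x$candidates)))
    cat(sprintf("  [%d] %.4f  %s\n", i, x$candidates$score[i],
                x$candidates$sentence[i]))
  invisible(x)
}

#' Save a trained translation model as a checkpoint directory
#'
#' Writes `config.json`, `vocab.txt` and a `weights.bin` blob.
#'
#' @param model An `nmt_model`.
#' @param dir Checkpoint directory (created if missing).
#' @export
save_nmt <- function(model, dir) {
  stopifnot(inherits(model, "nmt_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  writeLines(model$vocab, file.path(dir, "vocab.txt"))
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(model$params), con, size = 8)
  writeLines(as.character(signif(model$loss, 8)),
             file.path(dir, "loss.txt"))
  invisible(dir)
}

#' Load a translation model checkpoint written by [save_nmt()]
#' @param dir Checkpoint directory.
#' @return An `nmt_model`.
#' @export
load_nmt <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(nmt_config, cfg)
  vocab <- readLines(file.path(dir, "vocab.txt"), warn = FALSE)
  n <- file.size(file.path(dir, "weights.bin")) / 8
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  params <- readBin(con, "numeric", n = n, size = 8)
  loss <- as.numeric(readLines(file.path(dir, "loss.txt"), warn = FALSE))
  structure(list(params = params, vocab = vocab, config = config,
                 loss = loss), class = "nmt_model")
}
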