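# Internal helpers shared across modules.

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a named substream seed from a master seed so that the catalog,
# label, noise and date streams are independent: changing how one stream
# is consumed leaves the others untouched.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Zero-pad code identifiers to 5 characters (string-safe, codes may be
# alphanumeric).
pad_code <- function(x) {
  x <- as.character(x)
  n <- nchar(x)
  short <- !is.na(x) & n < 5L
  x[short] <- paste0(strrep("0", 5L - n[short]), x[short])
  x
}

collapse_ws <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
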