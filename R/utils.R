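# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string; used to derive independent-looking
# RNG substreams from a master seed plus arbitrary labels (gene ids,
# bootstrap replicate indices, ...). Keeping every intermediate below
# 2^53 makes the arithmetic exact in doubles.
hash_string <- function(s) {
  h <- 5381
  for (x in utf8ToInt(enc2utf8(as.character(s)))) {
    h <- (h * 33 + x) %% 2147483629
  }
  h
}

# Derive a seed from a master seed and any number of labels. Results are
# invariant to the order in which genes are processed because the stream
# depends only on (master, labels), never on global RNG state.
derive_seed <- function(master, ...) {
  as.integer(hash_string(paste(c(master, ...), collapse = "\r")) %% 2147483629 + 1)
}

# Evaluate `code` under a temporary RNG seed, restoring global state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
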