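# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream offset, keeping the
# result inside the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483629L) + 1L
}

# Evaluate expr under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

ws_tokens <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(character())
  strsplit(x, "\\s+")[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

stop_letex <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
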