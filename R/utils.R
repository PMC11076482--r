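# Internal helpers: error formatting, seeded evaluation, deterministic
# child seeds and a plain-text checksum for serialized training data.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warningf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a parent seed and a stage tag, so campaign
# stages can be regenerated independently. Result is in [0, 2^31 - 2].
child_seed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 7919 + h) %% m)
}

# Order-sensitive checksum of a numeric vector/matrix, printed as hex.
# Used to tag serialized models with a fingerprint of their training data.
data_checksum <- function(x) {
  s <- paste(sprintf("%.12g", as.numeric(x)), collapse = ",")
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% m
  sprintf("%08x", h)
}

# Half-up rounding (R's round() is round-half-even); used only at the
# presentation layer.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
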