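# Internal helpers shared across modules.

# Population (1/n) variance: makes yhat = mean(y) score exactly 0 in the
# pseudo-R^2, and matches the printed formula's variance(Y).
pop_var <- function(x) {
  x <- x[is.finite(x)]
  mean((x - mean(x))^2)
}

# Derive a stream-specific seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Missing-value spellings accepted on load (case-insensitive).
is_missing_token <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | tolower(x) %in% c("na", "nan")
}

# Parse a character vector as numeric; unparseable cells become NA.
parse_numeric <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  out[is_missing_token(x)] <- NA_real_
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
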