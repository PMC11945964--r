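#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif setNames predict
#' @importFrom utils head tail
NULL

# Error helpers: every user-facing failure carries a condition class so tests
# can assert on the failure mode, not on message wording.
abort_config   <- function(msg) abort(msg, class = "ebusfusion_error_config")
abort_geometry <- function(msg) abort(msg, class = "ebusfusion_error_geometry")
abort_shape    <- function(msg) abort(msg, class = "ebusfusion_error_shape")
abort_argument <- function(msg) abort(msg, class = "ebusfusion_error_argument")
abort_data     <- function(msg) abort(msg, class = "ebusfusion_error_data")
abort_label    <- function(msg) abort(msg, class = "ebusfusion_error_label")
abort_numeric  <- function(msg) abort(msg, class = "ebusfusion_error_numeric")
abort_key      <- function(msg) abort(msg, class = "ebusfusion_error_key")
abort_io       <- function(msg) abort(msg, class = "ebusfusion_error_io")

#' Derive a reproducible child seed from integer components
#'
#' Mixes any number of integers into a single seed in `[0, 2^31 - 2]` with a
#' multiplicative-congruential hash. Used to give every case and frame its own
#' RNG stream from one top-level seed, so cohorts regenerate byte-identically
#' without storing per-frame state.
#'
#' @param ... integers (or values coercible to integer) to mix.
#' @return a single integer seed.
#' @export
derive_seed <- function(...) {
  parts <- vapply(list(...), function(v) as.numeric(v)[1], numeric(1))
  s <- 11
  for (v in parts) {
    s <- (s * 69069 + (v %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x)

# FNV-1a style 32-bit hash of a character string, in pure double arithmetic.
# Used to fingerprint run configurations for idempotent resume.
string_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^24), b) + (h %/% 2^24) * 2^24) * 16777619) %% 2147483647
  sprintf("%08x", as.integer(h))
}
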