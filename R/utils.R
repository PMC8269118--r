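#' Derive a reproducible substream seed
#'
#' Mixes a base seed with one or more integer keys (e.g. consensus length n,
#' shuffle index) into a 31-bit seed, so independent work units get
#' independent, scheduling-invariant RNG streams.
#'
#' @param seed Base integer seed.
#' @param ... Integer keys identifying the work unit.
#' @return A single integer in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) {
    # 64-bit-safe mixing in double arithmetic, reduced mod 2^31 - 1
    h <- (h * 48271 + as.double(k) + 11) %% 2147483647
    h <- (h * 69621 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
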