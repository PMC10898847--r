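#' Numerically stable softmax over a vector of values
#'
#' @param v numeric vector of action values (logits).
#' @return probabilities summing to 1, each at least `1e-12`.
#' @keywords internal
softmax <- function(v) {
  p <- exp(v - max(v))
  p <- p / sum(p)
  pmax(p, 1e-12)
}

# Draw a sub-seed from a root seed without consuming the caller's RNG stream.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1009L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
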