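# Internal helpers: argument checking and deterministic seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_number <- function(x, name, finite = TRUE, positive = FALSE,
                          nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single numeric value", name), call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Protocol ensembles, per-source spike generators and Monte-Carlo
#' replicates each receive their own RNG sub-stream. The sub-stream seed is
#' a deterministic function of the experiment's master seed and an integer
#' stream index, via a multiplicative-congruential mix modulo the Mersenne
#' prime 2^31 - 1, so that all derived seeds stay within R's integer range.
#'
#' @param master integer master seed of the experiment.
#' @param stream non-negative integer sub-stream index.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(master, stream) {
  .check_number(master, "master")
  .check_number(stream, "stream", nonneg = TRUE)
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (abs(as.numeric(master)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.numeric(stream) + 1) * 8191) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 2) + 1)
}
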