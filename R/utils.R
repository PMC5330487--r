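# Internal helpers shared across modules.

#' Derive a named random substream seed from a master seed
#'
#' Every stochastic operation in the package draws its own seed from the
#' user-supplied master seed plus a stream label, so that e.g. the
#' permutation stream is independent of the genotype stream but both are
#' fully determined by one integer.
#'
#' @param seed integer master seed.
#' @param stream character label of the substream.
#' @return an integer seed in [1, 2^31 - 19].
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed),
            is.character(stream), length(stream) == 1L)
  mod <- 2147483629 # largest prime below 2^31
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% mod
  as.integer((abs(seed) %% mod + h) %% mod + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

assert_probabilities <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

# column variances of a numeric matrix, NA-aware
col_vars <- function(x) {
  n <- colSums(!is.na(x))
  mu <- colMeans(x, na.rm = TRUE)
  sq <- colMeans(x * x, na.rm = TRUE)
  out <- (sq - mu^2) * n / pmax(n - 1, 1)
  out[n < 2] <- NA_real_
  out
}
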