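#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm rpois runif sd pnorm pchisq qnorm cor
#' @importFrom utils read.csv write.csv
NULL

# Deterministic sub-seed derivation: every source of randomness in the
# package draws from a named substream of one root seed, so modules can be
# re-run independently and reproducibly. Arithmetic stays below 2^53 so the
# result is exact on all platforms; the returned seed is a positive 32-bit
# integer.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- abs(as.numeric(seed)) %% 2147483647
  for (ch in utf8ToInt(tag)) {
    s <- (s * 31 + ch) %% 2147483647
  }
  as.integer(max(s, 1))
}

# Population (divide-by-N) standard deviation. The coefficient of variation
# used throughout the package is sd_pop / mean; the divide-by-N convention is
# fixed so the CV = 1.0 aggregate threshold is reproducible.
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
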