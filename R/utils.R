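#' @useDynLib tomopict, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var sd fft approx quantile
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` with the global RNG seeded to `seed`, restoring the prior
# RNG state afterwards so library calls never clobber user-level randomness.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
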