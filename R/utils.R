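# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so generate_*/select* are pure functions of their arguments.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage sub-seed derived from a user seed; kept well below
# .Machine$integer.max.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147480000)
}

assertNumericVector <- function(x, what) {
  if (!is.numeric(x) || anyNA(x))
    stop(what, " must be numeric without missing values", call. = FALSE)
  invisible(x)
}
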