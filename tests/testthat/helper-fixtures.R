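# Shared fixture builders. Everything is generated in code at test time.

# Planted regression instance: y = 3 x3 - 2 x7 + noise, all other columns
# pure noise. Used by the selection-method oracles.
plantedInstance <- function(n = 60, p = 20, noiseSd = 0.05, seed = 404) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- 3 * X[, 3] - 2 * X[, 7] + rnorm(n, 0, noiseSd)
  list(X = X, y = y)
}

# Small, fast generator configuration for pipeline-level tests: a coarse
# grid and few replicates, but the same seven-level design and noise model.
smallConfig <- function(seed = 7L, ...) {
  generatorConfig(nPoints = 300L, replicates = 6L, seed = seed, ...)
}

# A noise-free configuration: every stochastic magnitude switched off.
noiselessConfig <- function(seed = 1L, ...) {
  generatorConfig(noiseSd = 0, scatterGainSd = 0, scatterOffsetSd = 0,
                  baselineScale = 0, backgroundJitterSd = 0, etalonSd = 0,
                  signalJitterSd = 0, seed = seed, ...)
}

# Distance from each wavenumber to the nearest true band center.
bandDistance <- function(wavenumbers, centers = carbendazimPeaks()$center) {
  vapply(wavenumbers, function(w) min(abs(w - centers)), numeric(1))
}
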