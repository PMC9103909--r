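#' Rank-stratified 2:1 calibration/prediction split
#'
#' Samples are first randomly arranged (seeded shuffle, which also breaks
#' ties), then sorted by reference value from high to low and grouped into
#' consecutive non-overlapping triplets; from every triplet exactly one
#' sample, chosen uniformly, goes to the prediction set. Leftover samples
#' (n mod 3) go to the calibration set, giving the 2:1 ratio.
#'
#' @param y numeric reference values, length >= 3.
#' @param seed integer seed.
#' @return a [SplitResult-class] with calibration and prediction indices.
#' @examples
#' sp <- rankStratifiedSplit(runif(252), seed = 1)
#' length(sp@calibration); length(sp@prediction)
#' @export
rankStratifiedSplit <- function(y, seed = 1L) {
  assertNumericVector(y, "y")
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples to form a 2:1 split")
  withSeed(seed, {
    shuffled <- sample.int(n)
    ord <- shuffled[order(y[shuffled], decreasing = TRUE)]
    nTriplets <- n %/% 3L
    pred <- integer(nTriplets)
    for (t in seq_len(nTriplets)) {
      triplet <- ord[(3L * t - 2L):(3L * t)]
      pred[t] <- triplet[sample.int(3L, 1L)]
    }
    methods::new("SplitResult",
                 calibration = sort(setdiff(seq_len(n), pred)),
                 prediction = sort(pred), seed = as.integer(seed))
  })
}

#' Fit a PLS1 regression model
#'
#' Classical NIPALS PLS1 with X-deflation: components are extracted
#' sequentially as covariance-maximising directions (for univariate y the
#' inner loop converges in one step), X is deflated by each score/loading
#' pair, and the regression vector is reconstructed as
#' `B = W (P'W)^{-1} q`. Data are centred internally; the returned
#' coefficients apply to raw spectra.
#'
#' @param X numeric matrix, samples x variables.
#' @param y numeric response (must not be constant).
#' @param nComponents latent variables requested; silently bounded by
#'   `min(n - 1, p)` and truncated with a warning if the deflated X runs out
#'   of covariance first.
#' @return a [PLSModel-class].
#' @examples
#' m <- plsFit(cbind(1:3), c(2, 4, 6), 1)
#' coef(m)
#' @export
plsFit <- function(X, y, nComponents) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (stats::var(y) < 1e-24) stop("y has zero variance; PLS1 is undefined")
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L) stop("nComponents must be >= 1")
  cap <- min(nrow(X) - 1L, ncol(X))
  if (nComponents > cap) {
    warning("nComponents reduced to the rank bound ", cap)
    nComponents <- cap
  }
  f <- cpp_pls1(X, y, nComponents)
  if (f$ncomp < nComponents)
    warning("deflated X exhausted; truncated to ", f$ncomp, " component(s)")
  k <- max(f$ncomp, 1L)
  methods::new("PLSModel",
    xMeans = as.numeric(f$xMeans), yMean = f$yMean,
    weights = f$weights, loadings = f$loadings, scores = f$scores,
    yLoadings = as.numeric(f$yLoadings),
    coefficients = as.numeric(f$coefPath[, k]),
    intercept = f$intercepts[k],
    coefPath = f$coefPath, nComponents = as.integer(k))
}

#' Predict from a PLS1 model
#'
#' @param object a [PLSModel-class].
#' @param newdata numeric matrix (samples x variables) or vector.
#' @param ... ignored.
#' @return numeric predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@coefficients))
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         length(object@coefficients))
  as.vector(newdata %*% object@coefficients) + object@intercept
})

#' @rdname predict-PLSModel-method
#' @param model a `PLSModel`.
#' @param X matrix of raw spectra.
#' @export
plsPredict <- function(model, X) predict(model, X)

#' Cross-validated RMSECV curve and latent-variable choice
#'
#' Samples are assigned to folds at random under the seed; for each
#' component count `k <= maxComponents` the root-mean-square error over all
#' held-out samples is computed. The chosen component count is the smallest
#' `k` whose RMSECV lies within 2% of the curve minimum (parsimony rule).
#'
#' @param X,y calibration data.
#' @param maxComponents upper bound on latent variables (default 15).
#' @param folds number of CV folds (default 10); every fold must receive at
#'   least one sample.
#' @param seed integer seed for the fold assignment.
#' @return list with `rmsecv` (length `maxComponents`), `nComponents`
#'   (chosen k), and `foldid` (the assignment used).
#' @export
plsCrossValidate <- function(X, y, maxComponents = 15L, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  maxComponents <- as.integer(maxComponents)
  if (folds < 2L) stop("folds must be >= 2")
  if (maxComponents < 1L) stop("maxComponents must be >= 1")
  if (folds > n) stop("more folds than samples: some folds would be empty")
  maxComponents <- min(maxComponents, n - ceiling(n / folds) - 1L, ncol(X))
  foldid <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  rmsecv <- as.numeric(cpp_pls_cv(X, y, seq_len(ncol(X)), foldid,
                                  maxComponents))
  k <- chooseComponents(rmsecv)
  list(rmsecv = rmsecv, nComponents = k, foldid = foldid)
}

# Parsimony rule: smallest k within 2% of the global RMSECV minimum.
chooseComponents <- function(rmsecv, window = 0.02) {
  which(rmsecv <= (1 + window) * min(rmsecv))[1L]
}

# Internal: RMSECV curve for a variable subset under a fixed fold
# assignment; returns the curve (used by the selection algorithms).
subsetRmsecv <- function(X, y, idx, foldid, kmax) {
  kmax <- min(kmax, length(idx))
  as.numeric(cpp_pls_cv(X, y, as.integer(idx), as.integer(foldid),
                        as.integer(kmax)))
}
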