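## The four wavelength-selection algorithms. All of them operate on the
## MSC-corrected calibration block, score candidate subsets by the minimum
## of a PLS1 RMSECV curve under one fixed, seeded fold assignment, and
## return a SelectionResult. Ties on RMSECV go to the smaller subset, then
## to the earlier iteration.

newSelection <- function(method, indices, X, rmsecvTrace, nVarTrace,
                         weights = numeric(), seed = 1L,
                         wavenumberAxis = NULL) {
  idx <- sort(unique(as.integer(indices)))
  wn <- if (is.null(wavenumberAxis)) as.numeric(idx) else wavenumberAxis[idx]
  methods::new("SelectionResult", method = method, indices = idx,
               wavenumbers = wn, rmsecvTrace = as.numeric(rmsecvTrace),
               nVarTrace = as.integer(nVarTrace),
               weights = as.numeric(weights), seed = as.integer(seed))
}

# 'Equal RMSECV' between candidate sets is read through the same 2%
# parsimony window used for the latent-variable choice: among candidates
# whose score is within 2% of the best, the smallest set wins, then the
# earlier iteration. With continuous CV scores exact ties never occur, and
# preferring the smaller of two statistically indistinguishable sets is
# the stated purpose of selection.
bestIteration <- function(scores, sizes, window = 0.02) {
  near <- which(scores <= (1 + window) * min(scores))
  near[order(sizes[near], near)][1L]
}

#' Bootstrapping soft shrinkage (BOSS) wavelength selection
#'
#' Iterative weighted-bootstrap selection with soft shrinkage. Each round:
#' (1) draw `nSubmodels` variable subsets by weighted bootstrap sampling
#' (the unique variables among `p` weighted draws with replacement);
#' (2) score every sub-model by its PLS RMSECV; (3) keep the
#' `bestFraction` lowest-RMSECV sub-models; (4) set each variable's new
#' weight to the sum, over kept sub-models, of its normalised absolute PLS
#' regression coefficient. Variables keep small non-zero weights rather
#' than being eliminated outright (the soft shrinkage), and only drop out
#' once no kept sub-model contains them. Rounds stop when the retained
#' count stops decreasing (or `maxIter`); the returned set is the round
#' with the lowest retained-set RMSECV.
#'
#' @param X MSC-corrected calibration spectra (samples x variables).
#' @param y reference concentrations.
#' @param nSubmodels bootstrap sub-models per round (default 500).
#' @param bestFraction fraction of sub-models kept (default 0.1).
#' @param folds CV folds used for scoring (default 5).
#' @param maxIter safety cap on rounds.
#' @param maxComponents latent-variable cap inside the scoring CV. Kept
#'   shallow (5): deep components let sub-model scores chase fold-level
#'   idiosyncrasies, which spreads the |beta| weights onto uninformative
#'   variables and stalls the shrinkage.
#' @param seed integer seed.
#' @param wavenumberAxis optional wavenumber axis for reporting.
#' @return a [SelectionResult-class].
#' @references Deng, B.-C. et al. (2016) A new method for wavelength
#'   interval selection that intelligently optimizes the locations, widths
#'   and combinations of the intervals. Analyst 141, 1876-1885 (iVISSA);
#'   Deng, B.-C. et al. (2016) A bootstrapping soft shrinkage approach for
#'   variable selection in chemical modeling. Anal. Chim. Acta 908, 63-74.
#' @export
bossSelect <- function(X, y, nSubmodels = 500L, bestFraction = 0.1,
                       folds = 5L, maxIter = 60L, maxComponents = 5L,
                       seed = 1L, wavenumberAxis = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  foldid <- withSeed(subSeed(seed, 1L), sample(rep_len(seq_len(folds), nrow(X))))
  if (p == 1L) {
    rc <- min(subsetRmsecv(X, y, 1L, foldid, maxComponents))
    return(newSelection("boss", 1L, X, rc, 1L, weights = 1, seed = seed,
                        wavenumberAxis = wavenumberAxis))
  }
  nKeep <- max(1L, ceiling(bestFraction * nSubmodels))
  withSeed(subSeed(seed, 2L), {
    w <- rep(1 / p, p)
    sets <- list()
    scores <- numeric()
    sizes <- integer()
    prevN <- p + 1L   # round 1 (equal weights) must always run
    stalled <- 0L
    for (it in seq_len(maxIter)) {
      foldid <- sample(rep_len(seq_len(folds), nrow(X)))  # fresh per round
      live <- which(w > 0)
      if (length(live) == 1L) {
        rc <- min(subsetRmsecv(X, y, live, foldid, maxComponents))
        sets[[it]] <- live; scores[it] <- rc; sizes[it] <- 1L
        if (it == 1L)
          warning("weights collapsed to a single variable; returning it")
        break
      }
      subs <- lapply(seq_len(nSubmodels), function(s)
        sort(unique(sample(live, p, replace = TRUE, prob = w[live]))))
      curves <- lapply(subs, function(v)
        subsetRmsecv(X, y, v, foldid, maxComponents))
      sc <- vapply(curves, min, numeric(1))
      sc[!is.finite(sc)] <- Inf
      kept <- order(sc)[seq_len(nKeep)]
      wNew <- numeric(p)
      for (ki in kept) {
        v <- subs[[ki]]
        kbest <- chooseComponents(curves[[ki]])  # parsimony rule, as in CV
        beta <- abs(cpp_pls_coef(X, y, as.integer(v), kbest)$beta)
        tot <- sum(beta)
        if (tot > 0) wNew[v] <- wNew[v] + beta / tot
      }
      if (all(wNew == 0)) break
      w <- wNew
      retained <- which(w > 0)
      sets[[it]] <- retained
      scores[it] <- min(subsetRmsecv(X, y, retained, foldid, maxComponents))
      sizes[it] <- length(retained)
      # 'stops decreasing' = stable across rounds; transient plateaus are
      # common while the weights are still concentrating
      stalled <- if (length(retained) >= prevN) stalled + 1L else 0L
      if (stalled >= 3L) break
      prevN <- min(prevN, length(retained))
    }
    if (length(sets) == 0L) {   # no sub-model ever produced usable weights
      sets[[1L]] <- seq_len(p)
      scores[1L] <- min(subsetRmsecv(X, y, seq_len(p), foldid, maxComponents))
      sizes[1L] <- p
    }
    best <- bestIteration(scores, sizes)
    newSelection("boss", sets[[best]], X, scores, sizes, weights = w,
                 seed = seed, wavenumberAxis = wavenumberAxis)
  })
}

#' Genetic-algorithm wavelength selection
#'
#' Binary chromosomes over the `p` wavelength variables, fitness equal to
#' minus the PLS RMSECV of the encoded subset (an empty chromosome is
#' unfit), tournament selection, uniform crossover, per-bit mutation and
#' elitist carry-over. Following the usual GA-wavelength-selection
#' practice for spectra with thousands of variables, chromosomes are
#' initialised sparse (`initVars` variables) and capped at `maxVars`
#' selected variables — without a cap, per-bit mutation alone drifts
#' chromosomes toward half the grid, and without scarcity there is no
#' pressure against harmless passenger variables. The best chromosome ever
#' evaluated is returned.
#'
#' @inheritParams bossSelect
#' @param popSize population size (default 64).
#' @param generations number of generations (default 100).
#' @param pCrossover per-pair uniform-crossover probability (default 0.5).
#' @param pMutation per-bit mutation probability (default 0.01).
#' @param elitism chromosomes carried over unchanged (default 1).
#' @param initVars variables per initial chromosome.
#' @param maxVars cap on selected variables per chromosome.
#' @return a [SelectionResult-class].
#' @export
gaSelect <- function(X, y, popSize = 64L, generations = 100L,
                     pCrossover = 0.5, pMutation = 0.01, elitism = 1L,
                     folds = 5L, maxComponents = 10L, initVars = 12L,
                     maxVars = 30L, seed = 1L, wavenumberAxis = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  foldid <- withSeed(subSeed(seed, 1L), sample(rep_len(seq_len(folds), nrow(X))))
  fitness <- function(bits) {
    v <- which(bits)
    if (length(v) == 0L) return(-Inf)
    -min(subsetRmsecv(X, y, v, foldid, maxComponents))
  }
  withSeed(subSeed(seed, 2L), {
    pop <- t(vapply(seq_len(popSize), function(i) {
      bits <- logical(p)
      bits[sample.int(p, min(initVars, p))] <- TRUE
      bits
    }, logical(p)))
    bestBits <- NULL
    bestScore <- Inf    # score of the returned chromosome
    minScore <- Inf     # best score ever seen (anchors the 2% tie window)
    traceR <- numeric(generations)
    traceN <- integer(generations)
    for (g in seq_len(generations)) {
      fit <- apply(pop, 1L, fitness)
      for (i in order(fit, decreasing = TRUE)[1:2]) {
        sc <- -fit[i]
        m <- sum(pop[i, ])
        minScore <- min(minScore, sc)
        # best-ever under the 2% near-tie rule: smaller subsets win among
        # statistically indistinguishable scores
        if (sc <= 1.02 * minScore &&
            (is.null(bestBits) || bestScore > 1.02 * minScore ||
             m < sum(bestBits) ||
             (m == sum(bestBits) && sc < bestScore))) {
          bestScore <- sc
          bestBits <- pop[i, ]
        }
      }
      traceR[g] <- bestScore
      traceN[g] <- sum(bestBits)
      if (g == generations) break
      elite <- pop[order(fit, decreasing = TRUE)[seq_len(elitism)], ,
                   drop = FALSE]
      tournament <- function() {
        i <- sample.int(popSize, 2L)
        pop[i[which.max(fit[i])], ]
      }
      children <- matrix(FALSE, popSize - elitism, p)
      for (c in seq_len(nrow(children))) {
        p1 <- tournament()
        child <- if (stats::runif(1) < pCrossover) {
          p2 <- tournament()
          mask <- stats::runif(p) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        # mutation at rate pMutation per retained variable (index
        # encoding): relocate, then occasionally add or drop one variable.
        # A per-grid-bit rate at p ~ 1400 would rewrite most of the
        # chromosome every generation and destroy inheritance.
        on <- which(child)
        move <- on[stats::runif(length(on)) < pMutation]
        if (length(move)) {
          child[move] <- FALSE
          child[sample.int(p, length(move))] <- TRUE
        }
        if (stats::runif(1) < pMutation) child[sample.int(p, 1L)] <- TRUE
        if (stats::runif(1) < pMutation && sum(child) > 1L)
          child[sample(which(child), 1L)] <- FALSE
        nOn <- sum(child)
        if (nOn == 0L) child[sample.int(p, 1L)] <- TRUE
        else if (nOn > maxVars)
          child[sample(which(child), nOn - maxVars)] <- FALSE
        children[c, ] <- child
      }
      pop <- rbind(elite, children)
    }
    newSelection("ga", which(bestBits), X, traceR, traceN, seed = seed,
                 wavenumberAxis = wavenumberAxis)
  })
}

#' LASSO coefficient path by cyclic coordinate descent
#'
#' Minimises `(1/2n) ||y - X b||^2 + lambda ||b||_1` over a decreasing
#' lambda grid with warm starts, on internally standardised variables
#' (zero mean, unit 1/n variance). The default grid is log-spaced from
#' `lambda_max = max |X's y_c| / n` (the smallest lambda with an all-zero
#' solution) down to `lambdaMinRatio * lambda_max`.
#'
#' @param X,y data (y is centred internally).
#' @param lambda optional positive, strictly decreasing grid.
#' @param nLambda,lambdaMinRatio default grid shape.
#' @param tol,maxit coordinate-descent convergence controls; `tol` is a
#'   relative tolerance on the decrease of the penalised objective per
#'   sweep.
#' @return list with `lambda`, `beta` (standardised scale, p x L),
#'   `betaRaw`, `intercept` (raw scale), and the standardisation
#'   (`center`, `scale`, `yMean`).
#' @export
lassoPath <- function(X, y, lambda = NULL, nLambda = 100L,
                      lambdaMinRatio = if (ncol(X) > nrow(X)) 1e-2 else 1e-4,
                      tol = 1e-9, maxit = 100000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  scale <- sqrt(colMeans(Xc^2))
  if (any(scale < 1e-12)) stop("constant column(s); cannot standardise")
  Xs <- sweep(Xc, 2L, scale, `/`)
  yMean <- mean(y)
  yc <- y - yMean
  if (is.null(lambda)) {
    lmax <- max(abs(crossprod(Xs, yc))) / n
    lambda <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                      length.out = nLambda))
  } else {
    if (any(lambda <= 0) || any(diff(lambda) >= 0))
      stop("lambda grid must be positive and strictly decreasing")
  }
  beta <- cpp_lasso_path(Xs, yc, lambda, tol, as.integer(maxit))
  betaRaw <- beta / scale
  intercept <- yMean - as.vector(crossprod(betaRaw, center))
  list(lambda = lambda, beta = beta, betaRaw = betaRaw,
       intercept = intercept, center = center, scale = scale, yMean = yMean)
}

#' LASSO wavelength selection (support of the 1-SE solution)
#'
#' Runs the coordinate-descent path, chooses lambda by k-fold
#' cross-validation with the one-standard-error rule, and returns the
#' non-zero support at that lambda. The downstream calibration model is a
#' PLS fit on the selected variables (LASSO-PLS), not the penalised fit.
#'
#' @inheritParams bossSelect
#' @inheritParams lassoPath
#' @return a [SelectionResult-class].
#' @export
lassoSelect <- function(X, y, nLambda = 100L,
                        lambdaMinRatio = if (ncol(X) > nrow(X)) 1e-2 else 1e-4,
                        folds = 5L, seed = 1L, wavenumberAxis = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  path <- lassoPath(X, y, nLambda = nLambda, lambdaMinRatio = lambdaMinRatio)
  foldid <- withSeed(subSeed(seed, 1L), sample(rep_len(seq_len(folds), n)))
  mseFold <- matrix(NA_real_, folds, length(path$lambda))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    pf <- lassoPath(X[tr, , drop = FALSE], y[tr], lambda = path$lambda)
    pred <- X[!tr, , drop = FALSE] %*% pf$betaRaw
    pred <- sweep(pred, 2L, pf$intercept, `+`)
    mseFold[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mseFold)
  cvse <- apply(mseFold, 2L, stats::sd) / sqrt(folds)
  iMin <- which.min(cvm)
  i1se <- which(cvm <= cvm[iMin] + cvse[iMin])[1L]
  support <- which(path$beta[, i1se] != 0)
  if (length(support) == 0L)
    stop("LASSO selected no variables at the 1-SE lambda (",
         signif(path$lambda[i1se], 3),
         "); all coefficients are zero at or above lambda_max")
  w <- numeric(ncol(X))
  w[support] <- abs(path$beta[support, i1se])
  newSelection("lasso", support, X, sqrt(cvm),
               colSums(path$beta != 0), weights = w, seed = seed,
               wavenumberAxis = wavenumberAxis)
}

#' iVISSA wavelength selection
#'
#' Interval variable iterative space shrinkage approach: a global weighted
#' binary matrix sampling phase searches the locations and combinations of
#' informative wavelengths, then a local phase widens each retained
#' wavelength into an interval. Globally, each of `nSamplings` binary rows
#' includes every variable independently with its current inclusion
#' probability (initialised at 0.5); rows are scored by PLS RMSECV, and
#' each probability is updated to the variable's inclusion frequency among
#' the best `ratio` fraction of rows, until the mean best-row RMSECV stops
#' improving. Locally, every variable with inclusion probability >= 0.5 is
#' expanded into symmetric intervals of up to `intervalHalfwidth` grid
#' steps, keeping expansions that reduce RMSECV.
#'
#' @inheritParams bossSelect
#' @param nSamplings binary rows per global iteration (default 500).
#' @param ratio fraction of best rows driving the update (default 0.1).
#' @param intervalHalfwidth maximum interval half-width in grid steps.
#' @return a [SelectionResult-class].
#' @export
ivissaSelect <- function(X, y, nSamplings = 500L, ratio = 0.1, folds = 5L,
                         maxIter = 15L, intervalHalfwidth = 7L,
                         maxComponents = 10L, seed = 1L,
                         wavenumberAxis = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  foldid <- withSeed(subSeed(seed, 1L), sample(rep_len(seq_len(folds), nrow(X))))
  nBest <- max(1L, ceiling(ratio * nSamplings))
  withSeed(subSeed(seed, 2L), {
    probs <- rep(0.5, p)
    traceR <- numeric()
    traceN <- integer()
    prevMean <- Inf
    flat <- 0L
    for (it in seq_len(maxIter)) {
      if (all(probs < 1e-8))
        stop("all inclusion probabilities collapsed to zero; ",
             "weaken the noise or increase nSamplings")
      B <- matrix(stats::runif(nSamplings * p) < rep(probs, each = nSamplings),
                  nSamplings, p)
      empty <- rowSums(B) == 0L
      if (any(empty))
        B[cbind(which(empty),
                sample.int(p, sum(empty), replace = TRUE))] <- TRUE
      sc <- vapply(seq_len(nSamplings), function(s)
        min(subsetRmsecv(X, y, which(B[s, ]), foldid, maxComponents)),
        numeric(1))
      sc[!is.finite(sc)] <- Inf
      best <- order(sc)[seq_len(nBest)]
      probs <- colMeans(B[best, , drop = FALSE])
      meanBest <- mean(sc[best])
      traceR <- c(traceR, meanBest)
      traceN <- c(traceN, sum(probs >= 0.5))
      # converged once the mean best-row RMSECV has stopped improving for
      # two consecutive iterations (single flat rounds occur while the
      # probabilities are still polarising)
      if (is.finite(prevMean) && meanBest >= prevMean * (1 - 1e-3)) {
        flat <- flat + 1L
        if (flat >= 2L) break
      } else flat <- 0L
      prevMean <- min(prevMean, meanBest)
    }
    cand <- which(probs >= 0.5)
    if (length(cand) == 0L)
      stop("no variable reached inclusion probability 0.5; ",
           "weaken the noise or increase nSamplings")
    base <- cand
    baseScore <- min(subsetRmsecv(X, y, base, foldid, maxComponents))
    for (ctr in cand[order(probs[cand], decreasing = TRUE)]) {
      bestSet <- NULL
      bestScore <- baseScore
      for (h in seq_len(intervalHalfwidth)) {
        interval <- max(1L, ctr - h):min(p, ctr + h)
        cand2 <- sort(union(base, interval))
        s2 <- min(subsetRmsecv(X, y, cand2, foldid, maxComponents))
        if (s2 < bestScore) {
          bestScore <- s2
          bestSet <- cand2
        }
      }
      if (!is.null(bestSet)) {
        base <- bestSet
        baseScore <- bestScore
      }
    }
    newSelection("ivissa", base, X, traceR, traceN, weights = probs,
                 seed = seed, wavenumberAxis = wavenumberAxis)
  })
}

#' Cluster selected wavelengths and report representatives
#'
#' Selected variable indices that are contiguous on the grid (gaps of at
#' most `maxGap` steps) are clustered; each cluster is reported by its
#' "peak-most" member — the variable maximising `score` (typically the
#' absolute covariance of the corrected intensities with the reference
#' concentration), or the cluster midpoint when no score is given. Mirrors
#' the convention of reporting a short wavelength list alongside a larger
#' selected-variable count.
#'
#' @param indices sorted selected variable indices.
#' @param wavenumberAxis the full wavenumber grid.
#' @param score optional per-variable relevance score (full-grid length).
#' @param maxGap largest index gap within a cluster (default 2).
#' @return data.frame with `index` (representative), `wavenumber`, `from`,
#'   `to`, `size`.
#' @export
clusterRepresentatives <- function(indices, wavenumberAxis, score = NULL,
                                   maxGap = 2L) {
  if (length(indices) == 0L) stop("no indices to cluster")
  idx <- sort(unique(as.integer(indices)))
  grp <- cumsum(c(1L, diff(idx) > maxGap))
  rows <- lapply(split(idx, grp), function(cl) {
    rep <- if (is.null(score)) cl[ceiling(length(cl) / 2)]
    else cl[which.max(score[cl])]
    data.frame(index = rep, wavenumber = wavenumberAxis[rep],
               from = wavenumberAxis[cl[1L]],
               to = wavenumberAxis[cl[length(cl)]], size = length(cl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
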