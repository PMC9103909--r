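methodLabels <- c(ivissa = "iVISSA-PLS", ga = "GA-PLS", lasso = "LASSO-PLS",
                  boss = "BOSS-PLS", full = "PLS (full spectrum)")

#' Run the full calibration pipeline
#'
#' Executes, fully seeded: dataset generation (or a supplied dataset) ->
#' rank-stratified 2:1 split -> MSC (reference fitted on the calibration
#' rows only) -> per-method wavelength selection on the corrected
#' calibration block -> PLS with a cross-validation-chosen latent-variable
#' count -> evaluation on the prediction set. With `"boss"` among the
#' methods and `spiked = TRUE`, a synthetic spiked validation set is also
#' generated, corrected with the calibration MSC reference, predicted with
#' the BOSS-PLS model, and summarised as spike-recovery statistics.
#'
#' @param config a [generatorConfig()]; defines the dataset (when
#'   `dataset` is `NULL`) and the spiked set.
#' @param dataset optional [SpectraSet-class] with known concentrations,
#'   used instead of generating one.
#' @param methods subset of `c("ivissa", "ga", "lasso", "boss")`, in report
#'   order; `character(0)` gives the full-spectrum PLS baseline only.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param folds,maxComponents final-model cross-validation controls.
#' @param selectionArgs named list of per-method argument overrides, e.g.
#'   `list(boss = list(nSubmodels = 200))`.
#' @param spiked logical, evaluate spike recovery with the BOSS-PLS model.
#' @param spikeLevels,spikeReplicates spiked-set design (mg/L, count).
#' @param verbose log each stage with its parameters via `message()`.
#' @return list with `reports` (one data.frame row per model), `models`,
#'   `selections`, `split`, `msc`, `recovery` (data.frame or `NULL`), and
#'   `spikePredictions`.
#' @examples
#' \donttest{
#' res <- runPipeline(generatorConfig(nPoints = 300L, replicates = 6L),
#'                    methods = "boss", spikeReplicates = 4L)
#' res$reports
#' }
#' @export
runPipeline <- function(config = generatorConfig(),
                        dataset = NULL,
                        methods = c("ivissa", "ga", "lasso", "boss"),
                        seed = config@seed,
                        folds = 10L, maxComponents = 15L,
                        selectionArgs = list(),
                        spiked = TRUE,
                        spikeLevels = c(0.1, 0.5, 1, 5, 10),
                        spikeReplicates = 10L,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  methods <- as.character(methods)
  bad <- setdiff(methods, c("ivissa", "ga", "lasso", "boss"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))

  if (is.null(dataset)) {
    say("simulate: %d levels x %d replicates, seed %d",
        length(config@concentrations), config@replicates, config@seed)
    dataset <- generateDataset(config)
  }
  y <- concentrations(dataset)
  if (anyNA(y)) stop("dataset has unknown concentrations; cannot calibrate")
  wn <- wavenumbers(dataset)

  split <- rankStratifiedSplit(y, seed = subSeed(seed, 11L))
  say("split: %d calibration / %d prediction (2:1, y-sorted triplets)",
      length(split@calibration), length(split@prediction))
  calSet <- dataset[, split@calibration]
  predSet <- dataset[, split@prediction]

  msc <- mscFit(calSet)
  corrCal <- mscCorrect(msc, calSet)
  corrPred <- mscCorrect(msc, predSet)
  Xc <- intensityMatrix(corrCal)
  yc <- concentrations(corrCal)
  Xp <- intensityMatrix(corrPred)
  yp <- concentrations(corrPred)
  say("msc: reference = mean of %d calibration spectra", nrow(Xc))

  relevance <- abs(as.vector(crossprod(Xc - rep(colMeans(Xc), each = nrow(Xc)),
                                       yc - mean(yc)))) / nrow(Xc)

  runs <- if (length(methods)) methods else "full"
  models <- list()
  selections <- list()
  reports <- list()
  for (i in seq_along(runs)) {
    m <- runs[i]
    if (m == "full") {
      idx <- seq_len(ncol(Xc))
      sel <- NULL
    } else {
      args <- c(list(X = Xc, y = yc, seed = subSeed(seed, 20L + i),
                     wavenumberAxis = wn),
                if (!is.null(selectionArgs[[m]])) selectionArgs[[m]])
      fun <- switch(m, boss = bossSelect, ga = gaSelect,
                    lasso = lassoSelect, ivissa = ivissaSelect)
      say("select[%s]: seed %d", m, args$seed)
      sel <- do.call(fun, args)
      idx <- sel@indices
      say("select[%s]: %d variables", m, length(idx))
    }
    cv <- plsCrossValidate(Xc[, idx, drop = FALSE], yc,
                           maxComponents = maxComponents, folds = folds,
                           seed = subSeed(seed, 40L + i))
    fit <- plsFit(Xc[, idx, drop = FALSE], yc, cv$nComponents)
    calPred <- predict(fit, Xc[, idx, drop = FALSE])
    prdPred <- predict(fit, Xp[, idx, drop = FALSE])
    reps <- clusterRepresentatives(idx, wn, score = relevance)
    reports[[m]] <- data.frame(
      method = methodLabels[[m]],
      nComponents = fit@nComponents,
      nSelected = length(idx),
      selectedWavelengths = paste(sprintf("%.0f", reps$wavenumber),
                                  collapse = "; "),
      rC = pearsonR(yc, calPred), rmsec = rmse(yc, calPred),
      rP = pearsonR(yp, prdPred), rmsep = rmse(yp, prdPred),
      rpd = rpd(yp, prdPred),
      stringsAsFactors = FALSE)
    say("model[%s]: k = %d, R_P = %.4f, RMSEP = %.4g, RPD = %.3g",
        m, fit@nComponents, reports[[m]]$rP, reports[[m]]$rmsep,
        reports[[m]]$rpd)
    models[[m]] <- fit
    if (!is.null(sel)) selections[[m]] <- sel
  }
  reportDf <- do.call(rbind, reports)
  rownames(reportDf) <- NULL

  recovery <- NULL
  spikePredictions <- NULL
  if (spiked && "boss" %in% runs) {
    say("spike: %d levels x %d replicates", length(spikeLevels),
        spikeReplicates)
    spikeSet <- generateSpikedSet(config, spikeLevels = spikeLevels,
                                  nReplicates = spikeReplicates,
                                  seed = subSeed(seed, 60L))
    corrSpike <- mscCorrect(msc, spikeSet)
    idx <- selections$boss@indices
    spikePredictions <- predict(models$boss,
                                intensityMatrix(corrSpike)[, idx, drop = FALSE])
    recovery <- recoveryStats(concentrations(corrSpike), spikePredictions)
    say("spike: recovery %.1f-%.1f%%, max RSD %.2f%%",
        min(recovery$recoveryMin), max(recovery$recoveryMax),
        max(recovery$rsd))
  }

  list(reports = reportDf, models = models, selections = selections,
       split = split, msc = msc, recovery = recovery,
       spikePredictions = spikePredictions,
       calibration = corrCal, prediction = corrPred)
}
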