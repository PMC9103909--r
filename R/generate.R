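#' Carbendazim SERS band library
#'
#' The eight major carbendazim SERS bands (629, 736, 770, 1007, 1227, 1271,
#' 1462 and 1521 1/cm) with their vibrational assignments. Widths (HWHM,
#' 1/cm) and relative amplitudes are generator conventions, not measured
#' values, and are freely configurable; the default width is narrow (2.5
#' 1/cm HWHM) so that, at the signal-to-noise ratio the validation
#' statistics demand, the informative halo of each band stays within about
#' 10 1/cm of its center (see the methods vignette).
#'
#' @return a data.frame with columns `center`, `width`, `amplitude`,
#'   `assignment`.
#' @examples
#' carbendazimPeaks()
#' @export
carbendazimPeaks <- function() {
  data.frame(
    center = c(629, 736, 770, 1007, 1227, 1271, 1462, 1521),
    width = 2.5,
    amplitude = c(1.0, 0.8, 0.6, 0.9, 1.0, 0.7, 0.6, 0.9),
    assignment = c(
      "ring stretching / C-C bending",
      "C-H bending in benzene ring",
      "C-H wagging",
      "C-N bending / C-C stretch / C-O-CH3 stretching",
      "C-C stretch / C-H bending / N-H bending",
      "C-H bending / N-H bending",
      "N-H bending / C-H bending",
      "N-H bending / C-N stretch"),
    stringsAsFactors = FALSE)
}

#' Synthetic band libraries for the interference panel
#'
#' Synthetic stand-in band libraries for the five pesticides of the
#' specificity test (chlorpyrifos, thiram, parathion-methyl, captan,
#' isocarbophos). Band positions are plausible but invented; by construction
#' no band lies within 15 1/cm of the 1225 1/cm carbendazim marker band, and
#' amplitudes are small to mimic the weak SERS affinity of non-adsorbing
#' interferents.
#'
#' @return a named list of peak data.frames (see [carbendazimPeaks()]).
#' @export
interferentPeaks <- function() {
  mk <- function(center, amplitude)
    data.frame(center = center, width = 6, amplitude = amplitude,
               assignment = "synthetic interferent band",
               stringsAsFactors = FALSE)
  list(
    chlorpyrifos = mk(c(632, 678, 975, 1090, 1570), c(0.4, 0.3, 0.5, 0.35, 0.3)),
    thiram = mk(c(560, 930, 1145, 1380, 1510), c(0.35, 0.3, 0.45, 0.5, 0.3)),
    `parathion-methyl` = mk(c(855, 1110, 1345, 1590), c(0.4, 0.35, 0.5, 0.3)),
    captan = mk(c(740, 1120, 1175, 1605), c(0.3, 0.4, 0.35, 0.3)),
    isocarbophos = mk(c(505, 842, 1015, 1650), c(0.35, 0.45, 0.4, 0.3)))
}

#' Synthetic displaced surface-species band library
#'
#' Bands of the citrate-like stabiliser layer on the SERS substrate, which
#' the analyte displaces as it adsorbs. In generated spectra these bands
#' appear as shallow dips growing with concentration, scaled internally so
#' that the net concentration signature (analyte bands minus displaced
#' bands) has zero spectral mean: the spectral mean that multiplicative
#' scatter correction removes per spectrum then carries no concentration
#' information, and wavelengths away from both band sets stay
#' uninformative. Positions and amplitudes are synthetic (no measured
#' species is reproduced); they avoid the analyte bands and the 1225 1/cm
#' specificity window.
#'
#' @return a data.frame with columns `center`, `width`, `amplitude`,
#'   `assignment`.
#' @export
displacedPeaks <- function() {
  data.frame(
    center = c(470, 565, 845, 955, 1395, 1640, 2080),
    width = 3,
    amplitude = c(0.6, 0.8, 1.0, 0.7, 0.9, 0.6, 0.5),
    assignment = "synthetic displaced surface-species band",
    stringsAsFactors = FALSE)
}

#' Noise-free unit-concentration band profile
#'
#' Sums one profile per band over the wavenumber grid. Lorentzian:
#' `a * w^2 / ((v - c)^2 + w^2)`; Gaussian: `a * exp(-log(2) (v - c)^2 / w^2)`
#' (`w` = HWHM). At its center an isolated band evaluates exactly to its
#' amplitude; neighbouring bands only add.
#'
#' @param peaks data.frame with `center`, `width`, `amplitude` (possibly
#'   zero rows, giving a zero profile).
#' @param wavenumbers strictly increasing numeric grid.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return numeric vector of length `length(wavenumbers)`.
#' @examples
#' wn <- seq(400, 2500, length.out = 1416)
#' prof <- peakProfile(carbendazimPeaks(), wn)
#' @export
peakProfile <- function(peaks, wavenumbers, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  assertNumericVector(wavenumbers, "wavenumbers")
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  out <- numeric(length(wavenumbers))
  if (is.null(peaks) || nrow(peaks) == 0L) return(out)
  if (any(peaks$width <= 0) || any(peaks$amplitude <= 0))
    stop("peak widths and amplitudes must be positive")
  rng <- range(wavenumbers)
  if (any(peaks$center < rng[1] | peaks$center > rng[2]))
    stop("peak center outside the wavenumber grid")
  for (i in seq_len(nrow(peaks))) {
    d2 <- (wavenumbers - peaks$center[i])^2
    w <- peaks$width[i]
    out <- out + if (shape == "lorentzian")
      peaks$amplitude[i] * w^2 / (d2 + w^2)
    else
      peaks$amplitude[i] * exp(-log(2) * d2 / w^2)
  }
  out
}

#' Generator configuration with the study-design defaults
#'
#' Defaults encode the calibration design emulated by the generator: seven
#' concentration levels (0.1, 0.5, 1, 5, 10, 20, 50 mg/L) with 36 replicates
#' each (252 spectra) on a 1416-point grid spanning 400-2500 1/cm, the
#' eight-band carbendazim library, a fixed smooth substrate background with
#' per-spectrum multiplicative gain and additive offset scatter, a random
#' quadratic baseline-drift term, and iid additive noise. The band profile
#' defaults to Gaussian and the concentration response to linear; Lorentzian
#' bands and a Langmuir response (`cSat`, mg/L) are available. See the
#' methods vignette for the rationale behind each default.
#'
#' @param gridMin,gridMax,nPoints wavenumber grid (1/cm).
#' @param concentrations,replicates calibration design (mg/L, count).
#' @param peaks band library data.frame.
#' @param displacement band library of the displaced surface species (see
#'   [displacedPeaks()]); a zero-row data.frame disables displacement.
#' @param shape band profile, `"gaussian"` or `"lorentzian"`.
#' @param response `"linear"` or `"langmuir"`.
#' @param cSat Langmuir saturation constant (mg/L).
#' @param backgroundScale multiplier of the fixed substrate background.
#' @param backgroundJitterSd relative s.d. of the per-spectrum rescaling of
#'   each smooth background component (substrate heterogeneity). Kept small
#'   by default: rescaling the components that make up the MSC reference
#'   perturbs the fitted scatter gain, which multiplies into the predicted
#'   concentration axis.
#' @param etalonSd s.d. (intensity units) of the per-spectrum amplitudes of
#'   the fixed fringe components (undulating background residuals of
#'   150-400 1/cm period, as left by etaloning or matrix variation). These
#'   are nearly orthogonal to the smooth MSC reference, so they mask the
#'   spectral-mean concentration leak at off-band wavelengths without
#'   disturbing the scatter correction; this is what keeps off-band
#'   wavelengths uninformative after MSC.
#' @param signalJitterSd relative s.d. of the independent per-band
#'   enhancement variability per spectrum (adsorption-geometry
#'   fluctuations modulating individual modes); a common component shared
#'   by all bands (hot-spot occupancy) is drawn with 0.2 times this s.d.
#'   Channels within one band share the fluctuation, so intra-band
#'   averaging saturates; the common component additionally caps what
#'   cross-band reweighting can recover, keeping the cross-validation
#'   curve flat in the component count, while staying small enough that
#'   its coupling into the calibration line leaves the lowest spike level
#'   within its relative-error budget. The floor both set is proportional
#'   to the level, mirroring how SERS replicate scatter grows with signal
#'   while leaving trace-level accuracy intact.
#' @param baselineDegree,baselineScale per-spectrum random polynomial drift.
#' @param scatterGainSd,scatterOffsetSd per-spectrum multiplicative /
#'   additive scatter (gain sd must stay below 1).
#' @param noiseSd additive iid noise sd (intensity units).
#' @param seed integer seed; generation is reproducible bit-for-bit.
#' @return a validated [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(seed = 7)
#' cfg
#' @export
generatorConfig <- function(gridMin = 400, gridMax = 2500, nPoints = 1416L,
                            concentrations = c(0.1, 0.5, 1, 5, 10, 20, 50),
                            replicates = 36L,
                            peaks = carbendazimPeaks(),
                            displacement = displacedPeaks(),
                            shape = "gaussian",
                            response = "linear", cSat = 100,
                            backgroundScale = 1, backgroundJitterSd = 0,
                            etalonSd = 0, signalJitterSd = 0.008,
                            baselineDegree = 2L, baselineScale = 0.002,
                            scatterGainSd = 0.05, scatterOffsetSd = 0.5,
                            noiseSd = 0.01, seed = 1L) {
  methods::new("GeneratorConfig",
    gridMin = gridMin, gridMax = gridMax, nPoints = as.integer(nPoints),
    concentrations = concentrations, replicates = as.integer(replicates),
    peaks = peaks, displacement = displacement,
    shape = shape, response = response, cSat = cSat,
    backgroundScale = backgroundScale,
    backgroundJitterSd = backgroundJitterSd, etalonSd = etalonSd,
    signalJitterSd = signalJitterSd,
    baselineDegree = as.integer(baselineDegree), baselineScale = baselineScale,
    scatterGainSd = scatterGainSd, scatterOffsetSd = scatterOffsetSd,
    noiseSd = noiseSd, seed = as.integer(seed))
}

#' Concentration-response law of a generator configuration
#'
#' Linear: `r(c) = c`. Langmuir: `r(c) = c / (1 + c / cSat)`, the adsorption
#' saturation law; as `cSat` grows it converges to the linear response.
#'
#' @param config a `GeneratorConfig`.
#' @param conc numeric concentrations (mg/L).
#' @return numeric response values.
#' @export
responseValue <- function(config, conc) {
  if (config@response == "linear") conc else conc / (1 + conc / config@cSat)
}

# Fixed smooth substrate/instrument background (arbitrary intensity counts),
# as independently rescalable smooth components. Two design constraints:
# (1) the background dominates the band signal so that MSC identifies the
# multiplicative scatter gain from the shared background rather than from
# the (concentration-dependent) analyte signature — with a weak background
# the fitted slope absorbs part of the response and the corrected
# calibration curve bends; (2) the per-spectrum jitter of the component
# amplitudes (substrate/matrix heterogeneity) gives off-band wavelengths
# genuine structured variance, without which every MSC-corrected wavelength
# would carry a nearly noise-free copy of the mean analyte signal (removed
# with each spectrum's own mean) and wavelength selection could not
# concentrate at the analyte bands.
backgroundComponents <- function(wavenumbers) {
  cbind(
    24000 * exp(-(wavenumbers - 400) / 900),
    15600 * exp(-0.5 * ((wavenumbers - 1800) / 500)^2),
    6000 * exp(-0.5 * ((wavenumbers - 1100) / 280)^2),
    4800 * exp(-0.5 * ((wavenumbers - 640) / 200)^2),
    rep(6000, length(wavenumbers)))
}

backgroundSpectrum <- function(wavenumbers)
  rowSums(backgroundComponents(wavenumbers))

# Fixed fringe shapes: smooth sinusoidal undulations whose periods are far
# shorter than any background component, hence nearly orthogonal to the MSC
# reference. Per-spectrum amplitudes are drawn N(0, etalonSd).
fringeComponents <- function(wavenumbers) {
  periods <- c(150, 210, 290, 400)
  phases <- c(0.3, 1.1, 2.0, 2.6)
  vapply(seq_along(periods), function(m)
    sin(2 * pi * wavenumbers / periods[m] + phases[m]),
    numeric(length(wavenumbers)))
}

gridOf <- function(config)
  seq(config@gridMin, config@gridMax, length.out = config@nPoints)

# Core simulator: one block of spectra sharing a peak library. `extra` is an
# optional per-spectrum additive in-scatter component (function of draw
# index) used for the spiked-set matrix background.
simulateBlock <- function(config, conc, reps, peaks, labels, extra = NULL) {
  wn <- gridOf(config)
  prof <- peakProfile(peaks, wn, config@shape)
  bgComp <- config@backgroundScale * backgroundComponents(wn)
  nComp <- ncol(bgComp)
  fringes <- fringeComponents(wn)
  nFr <- ncol(fringes)
  # competitive-adsorption displacement: the analyte displaces a surface
  # species whose bands shrink in proportion to the response, scaled so
  # the net signature has zero spectral mean — the spectral mean removed
  # by per-spectrum MSC centring then carries no concentration signal and
  # wavelengths away from both band sets stay uninformative.
  dprof <- peakProfile(config@displacement, wn, config@shape)
  gam <- if (sum(dprof) > 0 && sum(prof) > 0) sum(prof) / sum(dprof) else 0
  oneBand <- function(lib, i)
    peakProfile(lib[i, , drop = FALSE], wn, config@shape)
  PB <- if (nrow(peaks)) vapply(seq_len(nrow(peaks)), oneBand, lib = peaks,
                                numeric(length(wn))) else NULL
  DB <- if (nrow(config@displacement))
    vapply(seq_len(nrow(config@displacement)), oneBand,
           lib = config@displacement, numeric(length(wn))) else NULL
  tt <- if (config@nPoints > 1)
    2 * (wn - config@gridMin) / (config@gridMax - config@gridMin) - 1
  else 0
  n <- length(conc) * reps
  X <- matrix(0, n, config@nPoints)
  y <- numeric(n)
  ids <- character(n)
  k <- 0L
  for (ci in seq_along(conc)) {
    r <- responseValue(config, conc[ci])
    for (j in seq_len(reps)) {
      k <- k + 1L
      gain <- 1 + stats::rnorm(1L, 0, config@scatterGainSd)
      offset <- stats::rnorm(1L, 0, config@scatterOffsetSd)
      jitter <- 1 + stats::rnorm(nComp, 0, config@backgroundJitterSd)
      fr <- stats::rnorm(nFr, 0, config@etalonSd)
      sig <- prof - gam * dprof
      if (config@signalJitterSd > 0) {
        common <- stats::rnorm(1L, 0, 0.2 * config@signalJitterSd)
        if (!is.null(PB))
          sig <- sig + drop(PB %*% (common +
            stats::rnorm(ncol(PB), 0, config@signalJitterSd)))
        if (!is.null(DB) && gam > 0)
          sig <- sig - gam * drop(DB %*% (common +
            stats::rnorm(ncol(DB), 0, config@signalJitterSd)))
      }
      coefs <- stats::rnorm(config@baselineDegree + 1L, 0, config@baselineScale)
      base <- drop(outer(tt, 0:config@baselineDegree, `^`) %*% coefs)
      spec <- r * sig + drop(bgComp %*% jitter) +
        drop(fringes %*% fr) + base
      if (!is.null(extra)) spec <- spec + extra(k)
      noise <- stats::rnorm(config@nPoints, 0, config@noiseSd)
      X[k, ] <- gain * spec + offset + noise
      y[k] <- conc[ci]
      ids[k] <- sprintf("%s_c%g_r%02d", labels, conc[ci], j)
    }
  }
  SpectraSet(X, wn, concentrations = y, sampleIds = ids)
}

#' Generate a synthetic SERS calibration dataset
#'
#' Each spectrum is
#' `gain * (response(c) * profile + background + baseline) + offset + noise`
#' with `gain ~ N(1, scatterGainSd)`, `offset ~ N(0, scatterOffsetSd)`, a
#' random low-order polynomial baseline drift, and iid additive noise. The
#' run is a pure function of the configuration (including its seed).
#'
#' @param config a [generatorConfig()] object.
#' @return a [SpectraSet-class] with `replicates * length(concentrations)`
#'   spectra; the configuration is kept in `metadata(x)$config`.
#' @examples
#' set <- generateDataset(generatorConfig(nPoints = 200L, replicates = 3L))
#' nSpectra(set)
#' @export
generateDataset <- function(config) {
  methods::validObject(config)
  out <- withSeed(config@seed,
    simulateBlock(config, config@concentrations, config@replicates,
                  config@peaks, "cal"))
  S4Vectors::metadata(out)$config <- config
  out
}

#' Generate the interference panel for the specificity check
#'
#' One spectrum group per interfering pesticide plus a blank (baseline-only)
#' group. Every interferent library is checked against an exclusion window
#' around the carbendazim marker band: a band center inside
#' `exclusionCenter +/- exclusionWindow` is a configuration error.
#'
#' @param config a `GeneratorConfig` (grid, background and noise model).
#' @param interferents named list of peak data.frames; defaults to
#'   [interferentPeaks()].
#' @param concentration interferent concentration (mg/L), default 10.
#' @param replicates spectra per group.
#' @param exclusionCenter,exclusionWindow the protected marker band (1/cm).
#' @param seed integer seed (defaults to `config@seed + 1`).
#' @return named list of [SpectraSet-class] objects (interferents + `blank`).
#' @export
generateInterferents <- function(config, interferents = interferentPeaks(),
                                 concentration = 10, replicates = 6L,
                                 exclusionCenter = 1225, exclusionWindow = 15,
                                 seed = config@seed + 1L) {
  methods::validObject(config)
  for (nm in names(interferents)) {
    ctr <- interferents[[nm]]$center
    if (any(abs(ctr - exclusionCenter) <= exclusionWindow))
      stop(sprintf(
        "interferent '%s' has a band inside the %g +/- %g 1/cm exclusion window",
        nm, exclusionCenter, exclusionWindow))
  }
  blank <- data.frame(center = numeric(), width = numeric(),
                      amplitude = numeric(), assignment = character())
  libs <- c(interferents, list(blank = blank))
  withSeed(seed, {
    out <- lapply(names(libs), function(nm) {
      conc <- if (nm == "blank") 0 else concentration
      simulateBlock(config, conc, as.integer(replicates), libs[[nm]], nm)
    })
    names(out) <- names(libs)
    out
  })
}

#' Generate a spiked-sample validation set
#'
#' Emulates fortified real-matrix samples: on top of the calibration
#' signature each spectrum carries a matrix background distinct from the
#' calibration background (broad Gaussian humps with per-spectrum amplitude
#' jitter plus an elevated, partly random baseline). Reference
#' concentrations are set to the spike levels.
#'
#' @param config a `GeneratorConfig`; spike levels must lie within its
#'   calibrated concentration range.
#' @param spikeLevels spike concentrations (mg/L).
#' @param nReplicates replicate spectra per level (0 gives an empty set).
#' @param matrixBackground logical; disable to obtain pure calibration-law
#'   spectra (used by the additivity check).
#' @param matrixScale amplitude of the matrix humps (intensity units).
#' @param seed integer seed (defaults to `config@seed + 2`).
#' @return a [SpectraSet-class] with `length(spikeLevels) * nReplicates`
#'   spectra.
#' @export
generateSpikedSet <- function(config, spikeLevels = c(0.1, 0.5, 1, 5, 10),
                              nReplicates = 10L, matrixBackground = TRUE,
                              matrixScale = 0.005, seed = config@seed + 2L) {
  methods::validObject(config)
  rng <- range(config@concentrations)
  if (any(spikeLevels < rng[1] | spikeLevels > rng[2]))
    stop("spike levels must lie within the calibrated concentration range")
  nReplicates <- as.integer(nReplicates)
  wn <- gridOf(config)
  if (nReplicates == 0L) {
    out <- SpectraSet(matrix(0, 0, config@nPoints), wn,
                      concentrations = numeric(), sampleIds = character())
    return(out)
  }
  extra <- NULL
  if (matrixBackground) {
    humps <- data.frame(center = c(880, 1120, 1680, 1960),
                        width = c(35, 45, 40, 50),
                        amplitude = c(1, 0.8, 0.9, 0.7))
    shapes <- vapply(seq_len(nrow(humps)), function(i)
      exp(-log(2) * (wn - humps$center[i])^2 / humps$width[i]^2),
      numeric(length(wn)))
    tt <- 2 * (wn - config@gridMin) / (config@gridMax - config@gridMin) - 1
    extra <- function(k) {
      amps <- matrixScale * humps$amplitude * (1 + stats::rnorm(nrow(humps), 0, 0.2))
      lift <- stats::rnorm(1L, 5, 1) + stats::rnorm(1L, 0, 2 * config@baselineScale) * tt
      drop(shapes %*% amps) + lift
    }
  }
  out <- withSeed(seed,
    simulateBlock(config, spikeLevels, nReplicates, config@peaks, "spike",
                  extra = extra))
  S4Vectors::metadata(out)$spikeLevels <- spikeLevels
  out
}
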