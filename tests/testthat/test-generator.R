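test_that("peakProfile evaluates bands exactly at their centers", {
  wn <- seq(1200, 1250, by = 1)
  pk <- data.frame(center = 1225, width = 5, amplitude = 2)
  for (shape in c("lorentzian", "gaussian")) {
    prof <- peakProfile(pk, wn, shape)
    expect_equal(prof[wn == 1225], 2)
    expect_true(all(prof >= 0))
  }
})

test_that("peakProfile handles an empty library and rejects bad input", {
  wn <- seq(400, 500, length.out = 11)
  empty <- data.frame(center = numeric(), width = numeric(),
                      amplitude = numeric())
  expect_identical(peakProfile(empty, wn), rep(0, 11))
  expect_error(peakProfile(data.frame(center = 900, width = 5, amplitude = 1),
                           wn), "outside")
  expect_error(peakProfile(data.frame(center = 450, width = 5, amplitude = 1),
                           c(400, 390, 500)), "increasing")
})

test_that("default library puts local maxima at the eight reported bands", {
  wn <- seq(400, 2500, length.out = 1416)
  step <- diff(wn)[1]
  for (shape in c("gaussian", "lorentzian")) {
    prof <- peakProfile(carbendazimPeaks(), wn, shape)
    isMax <- which(diff(sign(diff(prof))) == -2) + 1L
    for (ctr in carbendazimPeaks()$center)
      expect_lte(min(abs(wn[isMax] - ctr)), step + 1e-9)
  }
})

test_that("default design yields 252 spectra on a 1416-point constant-step grid", {
  d <- generateDataset(generatorConfig(seed = 3))
  expect_equal(nSpectra(d), 252L)
  expect_equal(length(wavenumbers(d)), 1416L)
  expect_equal(as.vector(table(concentrations(d))), rep(36L, 7L))
  steps <- diff(wavenumbers(d))
  expect_equal(max(steps) - min(steps), 0, tolerance = 1e-9)
  expect_equal(steps[1], (2500 - 400) / (1416 - 1))
})

test_that("the generator is a pure function of its configuration", {
  cfg <- smallConfig(seed = 11L)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(intensityMatrix(a), intensityMatrix(b))
  c2 <- generateDataset(smallConfig(seed = 12L))
  expect_false(identical(intensityMatrix(a), intensityMatrix(c2)))
})

test_that("with all randomness off a blank spectrum is the pure baseline", {
  cfg <- noiselessConfig(nPoints = 200L, replicates = 2L)
  sets <- generateInterferents(cfg, replicates = 1L)
  blank <- intensityMatrix(sets$blank)[1L, ]
  expect_equal(blank, SERSelect:::backgroundSpectrum(wavenumbers(sets$blank)),
               ignore_attr = TRUE)
  zero <- noiselessConfig(nPoints = 200L, replicates = 2L,
                          backgroundScale = 0)
  blank0 <- intensityMatrix(generateInterferents(zero, replicates = 1L)$blank)
  expect_equal(as.vector(blank0), rep(0, 200L))
})

test_that("band intensity increases strictly with concentration (both laws)", {
  for (resp in c("linear", "langmuir")) {
    cfg <- noiselessConfig(nPoints = 500L, replicates = 1L, response = resp)
    d <- generateDataset(cfg)
    wn <- wavenumbers(d)
    X <- intensityMatrix(d)
    ord <- order(concentrations(d))
    for (ctr in c(629, 1227)) {
      j <- which.min(abs(wn - ctr))
      expect_true(all(diff(X[ord, j]) > 0), info = paste(resp, ctr))
    }
  }
})

test_that("the langmuir response converges to linear as cSat grows", {
  conc <- c(0.1, 0.5, 1, 5, 10, 20, 50)
  cfg <- generatorConfig(response = "langmuir", cSat = 1e9 * max(conc))
  expect_lt(max(abs(responseValue(cfg, conc) - conc) / conc), 1e-6)
})

test_that("interferent generation enforces the exclusion window", {
  cfg <- smallConfig()
  sets <- generateInterferents(cfg, replicates = 2L)
  expect_length(sets, 6L)
  expect_named(sets, c(names(interferentPeaks()), "blank"))
  for (nm in names(interferentPeaks())) {
    ctr <- interferentPeaks()[[nm]]$center
    expect_gt(min(abs(ctr - 1225)), 15)
  }
  bad <- list(x = data.frame(center = 1230, width = 6, amplitude = 0.5,
                             assignment = ""))
  expect_error(generateInterferents(cfg, interferents = bad), "exclusion")
})

test_that("spiked sets follow the five-level, replicated design", {
  cfg <- smallConfig()
  s <- generateSpikedSet(cfg, nReplicates = 10L)
  expect_equal(nSpectra(s), 50L)
  expect_equal(sort(unique(concentrations(s))), c(0.1, 0.5, 1, 5, 10))
  empty <- generateSpikedSet(cfg, nReplicates = 0L)
  expect_equal(nSpectra(empty), 0L)
  expect_error(generateSpikedSet(cfg, spikeLevels = 500), "calibrated")
})

test_that("without matrix background a spiked spectrum equals the calibration signature", {
  cfg <- noiselessConfig(nPoints = 250L, replicates = 1L)
  spiked <- generateSpikedSet(cfg, spikeLevels = 5, nReplicates = 1L,
                              matrixBackground = FALSE)
  cal <- generateDataset(noiselessConfig(nPoints = 250L, replicates = 1L,
                                         concentrations = 5))
  expect_equal(intensityMatrix(spiked), intensityMatrix(cal),
               ignore_attr = TRUE)
})

test_that("SpectraSet validates its geometry", {
  expect_error(SpectraSet(matrix(1, 2, 3), c(1, 2)), "length")
  expect_error(SpectraSet(matrix(1, 2, 2), c(2, 1)), "increasing")
  s <- SpectraSet(matrix(1:4, 2), c(1, 2), concentrations = c(1, NA))
  expect_equal(concentrations(s), c(1, NA))
  expect_equal(sampleIds(s), c("s001", "s002"))
})
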