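test_that("rmse matches its closed forms and a loop oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(numeric(), numeric()), "empty")
  expect_error(rmse(1:3, 1:2), "lengths")
  set.seed(14)
  a <- rnorm(100); b <- rnorm(100)
  acc <- 0
  for (i in 1:100) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(acc / 100))
})

test_that("pearsonR matches the covariance formula", {
  y <- c(1, 3, 2, 5)
  expect_equal(pearsonR(y, 2 * y + 1), 1)
  expect_equal(pearsonR(y, -y), -1)
  expect_error(pearsonR(y, rep(1, 4)), "constant")
  set.seed(15)
  a <- rnorm(50); b <- a + rnorm(50)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearsonR(a, b), num / den, tolerance = 1e-12)
})

test_that("RPD is SD over RMSEP, with the +Inf path on perfect prediction", {
  yt <- c(0, 1, 2)  # sd = 1
  expect_equal(rpd(yt, yt + c(0.25, -0.25, 0.25)), 4)
  expect_warning(r <- rpd(yt, yt), "\\+Inf")
  expect_identical(r, Inf)
  expect_error(rpd(rep(2, 5), rnorm(5)), "constant")
  set.seed(16)
  a <- rnorm(40); b <- a + rnorm(40, 0, 0.3)
  expect_equal(rpd(a, b), sd(a) / rmse(a, b), tolerance = 1e-12)
})

test_that("RPD * RMSEP equals the reference SD identically", {
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(sample(5:50, 1))
    b <- a + rnorm(length(a), 0, runif(1, 0.01, 2))
    expect_equal(rpd(a, b) * rmse(a, b), sd(a), tolerance = 1e-10)
  }
})

test_that("recovery statistics follow their closed forms", {
  out <- recoveryStats(rep(1, 3), c(0.9, 1.0, 1.1))
  expect_equal(out$recoveryMin, 90)
  expect_equal(out$recoveryMax, 110)
  expect_equal(out$rsd, 10)
  expect_equal(out$relErrMin, -10)
  expect_equal(out$relErrMax, 10)

  same <- recoveryStats(rep(2, 4), rep(1.5, 4))
  expect_equal(same$rsd, 0)

  mixed <- recoveryStats(c(0, 0, 0.1, 0.1), c(0.01, -0.01, 0.101, 0.099))
  expect_true(is.na(mixed$recoveryMin[mixed$level == 0]))
  expect_false(is.na(mixed$recoveryMin[mixed$level == 0.1]))
  expect_equal(mixed$meanPred[mixed$level == 0.1], 0.1)

  expect_error(recoveryStats(c(1, 2), c(1, 2)), ">= 2 replicates")
})

test_that("peak intensity is baseline-corrected band height", {
  wn <- seq(1150, 1300, by = 0.5)
  pk <- data.frame(center = 1225, width = 5, amplitude = 2)
  spec <- peakProfile(pk, wn, "lorentzian")
  expect_equal(peakIntensity(spec, wn, 1225, window = 50), 2, tolerance = 0.06)
  expect_equal(peakIntensity(rep(3, length(wn)), wn, 1225, window = 10), 0)
  # a gentle linear ramp is removed by the endpoint baseline interpolation
  ramp <- 5 + 0.005 * (wn - 1150)
  expect_equal(peakIntensity(spec + ramp, wn, 1225, window = 50), 2,
               tolerance = 0.06)
  expect_error(peakIntensity(spec, wn, 1140, window = 10), "outside")
  expect_error(peakIntensity(spec, wn, 1225, window = 0.2), "grid step")
})

test_that("the analyte marker band outshines every interferent at 1225 1/cm", {
  # raw spectra sit on a steep substrate background, so the comparison is
  # made the way a spectroscopist would: scatter-correct against the
  # blank-derived reference, subtract the mean blank, then read the
  # baseline-corrected band height at 1225 1/cm
  cfg <- generatorConfig(seed = 31)
  sets <- generateInterferents(cfg, replicates = 48L)
  carbSet <- generateDataset(generatorConfig(seed = 32,
                                             concentrations = 0.01,
                                             replicates = 48L))
  msc <- mscFit(sets$blank)
  wn <- wavenumbers(carbSet)
  blankMean <- colMeans(intensityMatrix(mscCorrect(msc, sets$blank)))
  netMean <- function(s)
    colMeans(intensityMatrix(mscCorrect(msc, s))) - blankMean
  carbI <- peakIntensity(netMean(carbSet), wn, 1225, window = 10)
  expect_gt(carbI, 0)
  for (nm in setdiff(names(sets), "blank")) {
    intI <- peakIntensity(netMean(sets[[nm]]), wn, 1225, window = 10)
    expect_lt(intI, carbI)
  }
})
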