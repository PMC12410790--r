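test_that("difference images keep the exact signed difference plus bias", {
  a <- matrix(100L, 10, 10)
  expect_true(all(differenceImage(a, a, bias = 500) == 500))
  expect_error(differenceImage(a, matrix(1L, 5, 5)), "shape")
  b <- a; b[1, 1] <- 103L
  d <- differenceImage(a, b, bias = 500)
  expect_identical(d[1, 1], 497)  # negatives are never truncated
})

test_that("difference of two read-noise frames has SD sqrt(2) x 30.3 ~ 42.9 GV", {
  spec <- paperSpec(darkCurrent = 0, cic = 0)
  f1 <- simulateFrame(spec, darkSettings(), seed = 61)
  f2 <- simulateFrame(spec, darkSettings(), seed = 62)
  d <- differenceImage(f1, f2, bias = 1000)
  expect_lt(abs(popSd(d) - 42.9) / 42.9, 0.015)
})

test_that("difference variance is the sum of the frame variances", {
  spec <- smallSpec(readNoise = 12, kRatio = 1.1)
  rel <- vapply(1:5, function(i) {
    f1 <- simulateFrame(spec, darkSettings(), seed = 100 + 2 * i)
    f2 <- simulateFrame(spec, darkSettings(), seed = 101 + 2 * i)
    obs <- popSd(differenceImage(f1, f2))^2
    expd <- popSd(framePixels(f1, 1))^2 + popSd(framePixels(f2, 1))^2
    obs / expd
  }, numeric(1))
  expect_lt(abs(mean(rel) - 1), 0.02)
})

test_that("i.i.d. read-noise frames pass the pixel-independence check", {
  spec <- paperSpec(darkCurrent = 0, cic = 0)
  st <- simulateStack(spec, darkSettings(), 5, masterSeed = 71)
  res <- checkPixelIndependence(st)
  expect_gt(res$similarity, 0.97)
  expect_identical(nrow(res$per_pair), 4L)
})

test_that("a fixed per-pixel pattern lowers observed below expected difference SD", {
  spec <- smallSpec(readNoise = 10, kRatio = 1)
  st <- simulateStack(spec, darkSettings(), 4, masterSeed = 72)
  shape <- dim(st@pixels)[1:2]
  pattern <- matrix(withr::with_seed(73, sample(0:40, prod(shape), TRUE)),
                    shape[1], shape[2])
  px <- st@pixels
  for (i in 1:4) px[, , i] <- px[, , i] + pattern
  patterned <- FrameStack(px, st@settings)
  res <- checkPixelIndependence(patterned)
  expect_lt(res$observed_sd, res$expected_sd)
  # the pattern cancels in differences: observed stays at the i.i.d. level
  clean <- checkPixelIndependence(st)
  expect_lt(abs(res$observed_sd - clean$observed_sd) / clean$observed_sd,
            0.02)
})

test_that("identical repeated frames give observed difference SD of zero", {
  m <- matrix(sample(90:110, 400, TRUE), 20, 20)
  st <- FrameStack(array(rep(m, 3), c(20, 20, 3)), darkSettings())
  res <- checkPixelIndependence(st)
  expect_identical(res$observed_sd, 0)
  expect_error(checkPixelIndependence(FrameStack(m, darkSettings())),
               "2 frames")
})

test_that("read noise is recovered from zero-exposure dark frames", {
  spec <- CameraSpec(readNoise = 10, kRatio = 2,
                     sensorShape = c(653L, 492L))
  st <- simulateStack(spec, darkSettings(), 5, masterSeed = 81)
  est <- estimateReadNoise(st, kRatio = 2)
  expect_lt(abs(est$value_e - 10) / 10, 0.03)
  # with K = 1 the electron value equals the gray-value SD
  est1 <- estimateReadNoise(st, kRatio = 1)
  expect_equal(est1$value_e, est$value_e * 2)
  expect_error(estimateReadNoise(simulateStack(spec, darkSettings(t = 10), 2,
                                               masterSeed = 82)),
               "0-s exposure")
})

test_that("the photon-transfer K estimator recovers the conversion ratio", {
  spec <- CameraSpec(readNoise = 12, kRatio = 2, darkCurrent = 0.5,
                     sensorShape = c(653L, 492L))
  scene <- PhotonScene(20000, spec@sensorShape)
  light <- simulateStack(spec, lightSettings(0.05), 10, scene,
                         masterSeed = 91)
  dark <- simulateStack(spec, darkSettings(0.05), 10, masterSeed = 92)
  est <- estimateKRatio(light, dark)
  expect_lt(abs(est$value - 2) / 2, 0.02)
  # pure Poisson electrons at K = 1: variance equals signal
  pois <- CameraSpec(kRatio = 1, sensorShape = c(300L, 240L))
  lp <- simulateStack(pois, lightSettings(0.05), 4,
                      PhotonScene(10000, pois@sensorShape), masterSeed = 93)
  dp <- simulateStack(pois, darkSettings(0.05), 4, masterSeed = 94)
  expect_lt(abs(estimateKRatio(lp, dp)$value - 1), 0.02)
})

test_that("K estimation rejects gained stacks and undetectable signal", {
  spec <- smallSpec(readNoise = 10, kRatio = 1.2, cic = 10)
  lg <- simulateStack(spec, lightSettings(0.05, 50), 2,
                      PhotonScene(100, spec@sensorShape), masterSeed = 95)
  dg <- simulateStack(spec, darkSettings(0.05, 50), 2, masterSeed = 96)
  expect_error(estimateKRatio(lg, dg), "unity gain")
  l0 <- simulateStack(spec, lightSettings(0.05), 2,
                      PhotonScene(0, spec@sensorShape), masterSeed = 97)
  d0 <- simulateStack(spec, darkSettings(0.05), 2, masterSeed = 98)
  expect_error(estimateKRatio(l0, d0), class = "camsnr_not_detected")
})

test_that("exposure bounds for negligible dark current follow 0.25 sigma^2/Dark", {
  expect_equal(maxNegligibleExposure(1, 1), 0.25)
  expect_equal(maxNegligibleExposure(1, 0.1), 2.5)
  expect_equal(maxNegligibleExposure(1, 0.001), 250)
  expect_identical(maxNegligibleExposure(5, 0), Inf)
})

test_that("dark current is recovered from a long-exposure series", {
  spec <- paperSpec(cic = 0)  # dark 2.5, read 25.3, K 1.2
  suite <- generateSuite(SuiteRecipe("dark_series", spec,
                                     exposures = c(120, 240, 360, 480, 600),
                                     nFrames = 3, masterSeed = 111))
  fit <- fitDarkCurrent(suite, kRatio = 1.2)
  expect_true(fit$detected)
  expect_lt(abs(fit$value - 2.5) / 2.5, 0.10)
  expect_identical(nrow(fit$per_exposure), 5L)
})

test_that("zero dark current is reported not-detected, never fitted as zero", {
  spec <- smallSpec(readNoise = 25.3, kRatio = 1.2, darkCurrent = 0)
  suite <- generateSuite(SuiteRecipe("dark_series", spec,
                                     exposures = c(100, 300, 600),
                                     nFrames = 2, masterSeed = 112))
  fit <- fitDarkCurrent(suite, kRatio = 1.2)
  if (!fit$detected) {
    expect_true(is.na(fit$value))
    expect_gt(fit$upper_bound_e_per_s, 0)
  } else {
    # statistical flukes may detect at single exposures; the fitted slope
    # must then be tiny relative to the read-noise variance scale
    expect_lt(fit$value * 600, 0.05 * 25.3^2)
  }
  expect_false(any(fit$per_exposure$isolated_var_e2 < 0))
})

test_that("short exposures sit in the negligible-dark flat region", {
  spec <- paperSpec(cic = 0)
  suite <- generateSuite(SuiteRecipe("dark_series", spec,
                                     exposures = c(20, 40, 60, 80),
                                     nFrames = 3, masterSeed = 113))
  fit <- fitDarkCurrent(suite, kRatio = 1.2)
  # Eq-12 logic: below t = 0.25 * read^2 / Dark = 64 s the isolated dark
  # SD stays under half the read noise
  bound <- maxNegligibleExposure(25.3, 2.5)
  expect_equal(bound, 64, tolerance = 0.01)
  below <- fit$per_exposure$exposure_s < bound
  expect_true(all(fit$per_exposure$isolated_sd_e[below] < 0.5 * 25.3 * 1.15))
})

test_that("photon shot noise scales as sqrt(t) across a shot series", {
  spec <- paperSpec(darkCurrent = 0, cic = 0,
                    sensorShape = c(300L, 240L))
  suite <- generateSuite(SuiteRecipe("shot_series", spec,
                                     exposures = c(0.02, 0.04, 0.06, 0.08),
                                     nFrames = 3, masterSeed = 121,
                                     flux = 40000))
  lights <- suite[grep("^light_", names(suite))]
  darks <- suite[grep("^dark_", names(suite))]
  res <- verifyShotNoiseScaling(lights, darks)
  expect_lt(res$max_rel_deviation, 0.05)
  # t = 4 t1 predicts exactly double the shortest-exposure noise
  tab <- res$per_exposure
  expect_equal(tab$predicted_sd_gv[tab$exposure_s == 0.08],
               2 * tab$observed_sd_gv[tab$exposure_s == 0.02])
})

test_that("zero flux makes photon noise undetectable, flagged not computable", {
  spec <- smallSpec(readNoise = 20, kRatio = 1.2)
  suite <- generateSuite(SuiteRecipe("shot_series", spec,
                                     exposures = c(0.02, 0.08),
                                     nFrames = 2, masterSeed = 122,
                                     flux = 0))
  lights <- suite[grep("^light_", names(suite))]
  # a stack measured against itself has exactly zero isolated photon noise
  expect_error(verifyShotNoiseScaling(lights, lights),
               class = "camsnr_not_detected")
})

test_that("EM gain is recovered from steady-source intensity ratios", {
  spec <- paperSpec(darkCurrent = 0)
  suite <- generateSuite(SuiteRecipe("gain_series", spec,
                                     gains = c(g3 = 103.5), exposures = 0.05,
                                     nFrames = 3, masterSeed = 131))
  est <- estimateEmGain(suite$light_g0, suite$dark_g0,
                        suite$light_g3, suite$dark_g3)
  expect_lt(abs(est$value - 103.5) / 103.5, 0.03)
  # gi = g0 gives gain 1
  same <- estimateEmGain(suite$light_g0, suite$dark_g0,
                         suite$light_g0, suite$dark_g0)
  expect_equal(same$value, 1)
})

test_that("the gain estimate is invariant to the source brightness", {
  spec <- smallSpec(readNoise = 15, kRatio = 1.3, cic = 10)
  ests <- vapply(c(2e4, 4e4), function(flux) {
    suite <- generateSuite(SuiteRecipe("gain_series", spec,
                                       gains = c(hi = 9.03),
                                       exposures = 0.05, nFrames = 3,
                                       masterSeed = 132, flux = flux))
    estimateEmGain(suite$light_g0, suite$dark_g0,
                   suite$light_hi, suite$dark_hi)$value
  }, numeric(1))
  expect_lt(abs(ests[1] - ests[2]) / ests[2], 0.02)
  expect_error(estimateEmGain(matrix(100L, 10, 10), matrix(200L, 10, 10),
                              matrix(300L, 10, 10), matrix(100L, 10, 10)),
               "denominator|positive")
})

test_that("clock-induced charge is recovered and averaged across gains", {
  spec <- paperSpec(darkCurrent = 0)  # CIC 25, read 25.3, K 1.2
  suite <- generateSuite(SuiteRecipe("gain_series", spec,
                                     gains = c(g1 = 2.40, g2 = 9.03,
                                               g3 = 103.5),
                                     exposures = 0.05, nFrames = 3,
                                     masterSeed = 141))
  d0 <- darkImageStats(suite$dark_g0)
  per <- vapply(c(g1 = 2.40, g2 = 9.03, g3 = 103.5), function(g) {
    lab <- names(which(c(g1 = 2.40, g2 = 9.03, g3 = 103.5) == g))
    estimateCic(d0, darkImageStats(suite[[paste0("dark_", lab)]]),
                emGain = g, kRatio = 1.2)$value
  }, numeric(1))
  expect_lt(abs(mean(per) - 25) / 25, 0.10)
  expect_error(estimateCic(d0, d0, emGain = 1), "> 1")
})

test_that("zero CIC and dark give matching dark variances and a zero estimate", {
  spec <- smallSpec(readNoise = 20, kRatio = 1.2, cic = 0)
  d0 <- simulateStack(spec, darkSettings(0.01, 1), 4, masterSeed = 142)
  dg <- simulateStack(spec, darkSettings(0.01, 50), 4, masterSeed = 143)
  est <- estimateCic(d0, dg, emGain = 50, kRatio = 1.2)
  expect_gte(est$value, 0)
  expect_lt(est$value, 0.1)
  ratio <- darkImageStats(dg)$sd_gv / darkImageStats(d0)$sd_gv
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("the literature CIC badly under-predicts a high-CIC dark frame", {
  spec <- paperSpec(darkCurrent = 0)  # fitted CIC 25
  fr <- simulateFrame(spec, darkSettings(0.01, 103.5), seed = 151)
  observed <- popSd(framePixels(fr, 1))
  litSpec <- paperSpec(cic = 4, readNoise = 30.3 / 1.2)
  predicted <- theoreticalNoiseBudget(litSpec,
                                      darkSettings(0, 103.5))@grayValues[["sd_total"]]
  expect_gt(observed / predicted, 2)
})

test_that("estimator error shrinks roughly as 1/sqrt(pixels)", {
  spec <- CameraSpec(readNoise = 10, kRatio = 1, sensorShape = c(256L, 256L))
  roiSmall <- ROI(0, 0, 64, 64)
  roiLarge <- ROI(0, 0, 256, 256)
  errs <- vapply(1:12, function(i) {
    st <- simulateStack(spec, darkSettings(), 1, masterSeed = 1000 + i)
    c(abs(estimateReadNoise(st, roiSmall, 1)$value_e - 10),
      abs(estimateReadNoise(st, roiLarge, 1)$value_e - 10))
  }, numeric(2))
  # 16x the pixels: RMS error should fall ~4x (allow wide MC slack)
  ratio <- sqrt(mean(errs[1, ]^2)) / sqrt(mean(errs[2, ]^2))
  expect_gt(ratio, 2)
})

test_that("the full calibrate pipeline recovers randomized camera parameters", {
  nSpecs <- 20
  draws <- withr::with_seed(2024, data.frame(
    read = stats::runif(nSpecs, 5, 50),
    k = stats::runif(nSpecs, 0.5, 3),
    dark = stats::runif(nSpecs, 0.1, 5),
    cic = stats::runif(nSpecs, 2, 30),
    gain = exp(stats::runif(nSpecs, log(2), log(150)))
  ))
  failures <- character()
  for (i in seq_len(nSpecs)) {
    d <- draws[i, ]
    # ADC offset sized so dark frames never clip at zero even for the
    # largest read-noise x K draws (real cameras set the bias this way)
    spec <- CameraSpec(readNoise = d$read, kRatio = d$k, darkCurrent = d$dark,
                       cic = d$cic, bias = 2000,
                       sensorShape = c(326L, 246L))
    ms <- 3000 + i
    brightFlux <- 15000 / 0.08   # ~15000 e- at the longest exposure
    suites <- list(
      read_noise = generateSuite(SuiteRecipe("read_noise", spec, nFrames = 5,
                                             masterSeed = ms))$read_noise,
      shot_series = generateSuite(SuiteRecipe("shot_series", spec,
                                              exposures = c(0.02, 0.08),
                                              nFrames = 6, masterSeed = ms + 1,
                                              flux = brightFlux)),
      dark_series = generateSuite(SuiteRecipe("dark_series", spec,
                                              exposures = c(120, 240, 360,
                                                            480, 600),
                                              nFrames = 2,
                                              masterSeed = ms + 2)),
      gain_series = generateSuite(SuiteRecipe("gain_series", spec,
                                              gains = c(gi = d$gain),
                                              exposures = 0.02, nFrames = 4,
                                              masterSeed = ms + 3))
    )
    rep <- calibrate(suites, roi = defaultRoi(spec@sensorShape, 0.5))
    note <- function(what) failures <<- c(failures,
                                          sprintf("spec %d (%s)", i, what))
    if (abs(rep@kRatio$value - d$k) / d$k > 0.03) note("K")
    if (abs(rep@readNoise$value_e - d$read) / d$read > 0.03) note("read")
    if (abs(rep@emGain[["gi"]] - d$gain) / d$gain > 0.10) note("gain")
    # dark current has power only when the series reaches past the
    # negligibility bound; otherwise the flag semantics are checked instead
    if (maxNegligibleExposure(d$read, d$dark) < 300) {
      if (!isTRUE(rep@darkCurrent$detected) ||
          abs(rep@darkCurrent$value - d$dark) / d$dark > 0.10) note("dark")
    }
    # CIC precision scales with EN^2 Gain^2 / read^2; require recovery when
    # the amplified CIC dominates the read-noise variance
    if (2 * d$gain^2 * d$cic > 5 * d$read^2) {
      if (abs(rep@cic$average - d$cic) / d$cic > 0.10) note("CIC")
    }
    if (length(rep@cic) && rep@cic$average < 0) note("negative CIC")
  }
  expect_identical(failures, character(0))
})
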