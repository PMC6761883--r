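test_that("cone mosaic generator conserves counts and flags borders", {
  f <- generateConeMosaic(12000, seed = 1, noiseSd = 0, touchingFraction = 0)
  truth <- f$truth
  expect_equal(truth@nTotal + truth@nExcludable, nrow(truth@positionsUm))
  expect_equal(truth@nTotal, sum(!truth@borderFlag))
  # positions lie inside the field
  expect_true(all(truth@positionsUm[, 1] >= 0 & truth@positionsUm[, 1] <= 167.6))
  expect_true(all(truth@positionsUm[, 2] >= 0 & truth@positionsUm[, 2] <= 223.8))
  # placed count matches density * area
  expect_equal(nrow(truth@positionsUm), round(12000 * 223.8e-3 * 167.6e-3))
  # image dimensions from pixel size
  expect_equal(dim(pixels(f$image)), c(round(167.6 / 0.32), round(223.8 / 0.32)))
})

test_that("cone mosaic generator handles degenerate and invalid inputs", {
  tiny <- generateConeMosaic(1e-4, 50, 50, seed = 1, noiseSd = 0,
                             touchingFraction = 0)
  expect_equal(tiny$truth@nTotal, 0L)
  expect_true(all(pixels(tiny$image) == 0))
  expect_error(generateConeMosaic(-5, seed = 1), "positive")
  expect_error(generateConeMosaic(1000, pxUm = 0, seed = 1), "positive")
  expect_error(generateConeMosaic(1000, touchingFraction = 0.9, seed = 1),
               "0, 0.5")
  expect_error(generateConeMosaic(8e5, 50, 50, seed = 1),
               "infeasible density")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generateConeMosaic(8000, 80, 80, seed = 7, noiseSd = 3)
  b <- generateConeMosaic(8000, 80, 80, seed = 7, noiseSd = 3)
  c <- generateConeMosaic(8000, 80, 80, seed = 8, noiseSd = 3)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth@positionsUm, b$truth@positionsUm)
  expect_false(identical(a$truth@positionsUm, c$truth@positionsUm))

  t1 <- generateRPETile(17, seed = 3, noiseSd = 2)
  t2 <- generateRPETile(17, seed = 3, noiseSd = 2)
  expect_identical(greenChannel(t1$tile), greenChannel(t2$tile))
  expect_identical(t1$truth@punctaIdx, t2$truth@punctaIdx)

  e1 <- generateERGTrace(ERGTruth(), noiseSd = 5, seed = 4)
  e2 <- generateERGTrace(ERGTruth(), noiseSd = 5, seed = 4)
  expect_identical(voltages(e1), voltages(e2))

  o1 <- generateONLTable(data.frame(name = "g", meanRows = 10, cvPercent = 8,
                                    nMice = 3, nFields = 12), seed = 5)
  o2 <- generateONLTable(data.frame(name = "g", meanRows = 10, cvPercent = 8,
                                    nMice = 3, nFields = 12), seed = 5)
  expect_identical(o1, o2)

  w1 <- generateWholeRetina(5000, seed = 6)
  w2 <- generateWholeRetina(5000, seed = 6)
  expect_identical(w1@positionsMm, w2@positionsMm)
})

test_that("whole-retina generator respects count, geometry and gradient", {
  wr <- generateWholeRetina(100, retinaAreaMm2 = 1, seed = 2)
  expect_equal(nrow(wr@positionsMm), 100L)
  expect_true(all(sqrt(rowSums(wr@positionsMm^2)) <= sqrt(1 / pi) + 1e-12))

  # gradient > 0: the inner disk of half the area holds more points than
  # the outer annulus of equal area (Monte-Carlo check)
  wg <- generateWholeRetina(1e5, retinaAreaMm2 = 15, gradient = 0.8, seed = 3)
  r <- sqrt(rowSums(wg@positionsMm^2))
  Rhalf <- sqrt(15 / (2 * pi))
  expect_gt(sum(r <= Rhalf), sum(r > Rhalf))
  # and for a uniform retina the two halves are statistically even
  wu <- generateWholeRetina(1e5, retinaAreaMm2 = 15, gradient = 0, seed = 3)
  ru <- sqrt(rowSums(wu@positionsMm^2))
  expect_lt(abs(sum(ru <= Rhalf) - 5e4), 4 * sqrt(1e5 * 0.25))
})

test_that("RPE tile generator builds a maskable two-channel structure", {
  g0 <- generateRPETile(20, punctaCount = 0, noiseSd = 0, seed = 1)
  expect_true(all(redChannel(g0$tile) == 0))
  # no autofluorescence: masked and unmasked green means agree
  m <- autofluorescenceMask(g0$tile)
  expect_equal(mean(greenChannel(g0$tile)[m]), mean(greenChannel(g0$tile)))

  g <- generateRPETile(20, punctaCount = 25, punctaGreen = 200,
                       punctaRed = 50, noiseSd = 0, seed = 2)
  tru <- g$truth
  expect_gt(length(tru@punctaIdx), 0)
  # puncta in both channels at identical coordinates
  expect_true(all(greenChannel(g$tile)[tru@punctaIdx] == 200))
  expect_true(all(redChannel(g$tile)[tru@punctaIdx] == 50))
  expect_true(all(redChannel(g$tile)[-tru@punctaIdx] == 0))
  # closed-form mixture mean of the constructed image
  n <- length(greenChannel(g$tile))
  nJ <- length(setdiff(tru@junctionIdx, tru@punctaIdx))
  expected <- (nJ * 20 + length(tru@punctaIdx) * 200) / n
  expect_equal(mean(greenChannel(g$tile)), expected, tolerance = 1e-12)
  expect_gt(mean(greenChannel(g$tile)), 0)
  expect_error(generateRPETile(300, seed = 1), "0, 255")
})

test_that("ERG trace generator meets its trivial constructions", {
  flat <- generateERGTrace(ERGTruth(0, 0, rep(0, 4)), noiseSd = 0)
  expect_true(all(voltages(flat) == 0))

  tr <- generateERGTrace(ERGTruth(150, 400, rep(0, 4), bPeakTime = 0.077),
                         fs = 5000, noiseSd = 0)
  v <- voltages(tr); t <- times(tr)
  expect_true(all(v[t < stimulusOnset(tr)] == 0))
  # trough reaches -aAmp (construction tolerance: the slow wave is
  # calibrated under the OP-suppressed measurement convention, so the raw
  # trough approximates the design while the extracted features match it
  # exactly)
  expect_equal(min(v), -150, tolerance = 0.08)
  expect_equal(aWaveAmplitude(tr), 150, tolerance = 0.01)
  # b-peak at the designed latency within one sample
  expect_lt(abs(t[which.max(v)] - stimulusOnset(tr) - 0.077), 1 / 5000 + 1e-12)
  expect_equal(max(v) - min(v), 400, tolerance = 0.03)
  expect_equal(bWaveAmplitude(tr)$bAmpUv, 400, tolerance = 0.01)

  expect_error(generateERGTrace(ERGTruth(), fs = 500), ">= 1000")
  expect_error(generateERGTrace(ERGTruth(opFreq = 600), fs = 1000), "Nyquist")
  expect_error(generateERGTrace(ERGTruth(bPeakTime = 0.4), durationS = 0.3),
               "cover")
  expect_error(ERGTruth(aAmp = 200, bAmp = 100), "bAmp")
})

test_that("ONL table generator matches its group specification", {
  spec0 <- data.frame(name = "z", meanRows = 9, cvPercent = 0,
                      nMice = 2, nFields = 8)
  tab0 <- generateONLTable(spec0, seed = 1)
  expect_true(all(tab0$rows == 9))
  expect_equal(nrow(tab0), 16L)
  expect_equal(length(unique(tab0$eccentricity)), 4L)

  # law-of-large-numbers calibration at inflated n
  spec <- data.frame(name = "WT", meanRows = 11.2, cvPercent = 8.5,
                     nMice = 40, nFields = 12)
  tab <- generateONLTable(spec, seed = 2)
  expect_equal(mean(tab$rows), 11.2, tolerance = 0.02)
  cv <- 100 * sd(tab$rows) / mean(tab$rows)
  expect_equal(cv, 8.5, tolerance = 0.15)
  expect_error(generateONLTable(data.frame(name = "x", meanRows = -1,
                                           cvPercent = 5, nMice = 2,
                                           nFields = 4), seed = 1),
               "positive")
})

test_that("generator moments are statistically calibrated across replicates", {
  # mosaic: placed count is deterministic given density; blob peak level
  # and noise behave as specified across replicates
  ms <- replicate(30, {
    f <- generateConeMosaic(8000, 60, 60, seed = sample.int(1e6, 1),
                            noiseSd = 4, touchingFraction = 0)
    mean(pixels(f$image)[pixels(f$image) > 100])
  })
  expect_lt(abs(mean(ms) - mean(ms[1])) / mean(ms), 0.2)

  set.seed(42)
  onl <- replicate(60, {
    tab <- generateONLTable(data.frame(name = "g", meanRows = 10,
                                       cvPercent = 10, nMice = 4,
                                       nFields = 12),
                            seed = sample.int(1e6, 1))
    mean(tab$rows)
  })
  se <- (10 * 0.10) / sqrt(48)   # sd of one replicate's mean
  expect_lt(abs(mean(onl) - 10), 3 * se / sqrt(60))
})
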