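mkTrace <- function(v, fs = 2000, onset = 0.05, ...) {
  t <- seq(0, by = 1 / fs, length.out = length(v))
  ERGTrace(t = t, v = v, onset = onset, ...)
}

test_that("baseline and offset invariance hold for all features", {
  flat <- mkTrace(rep(0, 500))
  expect_equal(ergBaseline(flat), 0)
  expect_equal(ergBaseline(mkTrace(rep(5, 500))), 5)
  expect_error(ergBaseline(mkTrace(rep(0, 500), onset = 0.001)), "10 ms")

  tr <- generateERGTrace(ERGTruth(150, 400, c(40, 30, 20, 10)), noiseSd = 0)
  off <- methods::initialize(tr, v = voltages(tr) + 37)
  f1 <- ergFeatures(tr); f2 <- ergFeatures(off)
  # filter edge transients at the shifted record ends allow sub-0.2%
  # discrepancies; the features themselves are offset-invariant
  expect_equal(f1@aAmpUv, f2@aAmpUv, tolerance = 2e-3)
  expect_equal(f1@bAmpUv, f2@bAmpUv, tolerance = 2e-3)
  expect_equal(f1@opAmpsUv, f2@opAmpsUv, tolerance = 2e-3)
})

test_that("a-wave is read at 7 ms with the documented edge behavior", {
  tr <- generateERGTrace(ERGTruth(150, 400, rep(0, 4)), fs = 5000,
                         noiseSd = 0)
  expect_equal(aWaveAmplitude(tr), 150, tolerance = 0.02)
  expect_equal(aWaveAmplitude(mkTrace(rep(0, 500))), 0)
  short <- mkTrace(rep(0, 110), onset = 0.052)
  expect_error(aWaveAmplitude(short), "record ends")
})

test_that("b-wave amplitude and latency recover the design", {
  tr <- generateERGTrace(ERGTruth(150, 400, rep(0, 4), bPeakTime = 0.077),
                         fs = 5000, noiseSd = 0)
  b <- bWaveAmplitude(tr)
  expect_equal(b$bAmpUv, 400, tolerance = 0.02)
  expect_lt(abs(b$bPeakTimeS - 0.077), 1 / 5000 + 1e-12)

  expect_error(bWaveAmplitude(mkTrace(rep(0, 500))), "feature not found")

  # pure positive lobe: measured from baseline, with a warning
  pos <- generateERGTrace(ERGTruth(0, 300, rep(0, 4), bPeakTime = 0.08),
                          fs = 2000, noiseSd = 0)
  expect_warning(bp <- bWaveAmplitude(pos), "baseline")
  expect_equal(bp$bAmpUv, 300, tolerance = 0.03)
})

test_that("the OP band-pass has the stated frequency response", {
  fs <- 5000
  t <- seq(0, 0.4, by = 1 / fs)
  inBand <- ERGTrace(t, sin(2 * pi * 120 * t), onset = 0.05)
  out <- extractOPs(inBand, order = 5, bandHz = c(60, 300))
  mid <- voltages(out)[t > 0.1 & t < 0.3]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)

  # zero-phase: the peak within one specific carrier cycle is preserved
  # within one sample
  cyc <- t >= 0.2 & t < 0.2 + 1 / 120
  pkIn <- t[cyc][which.max(voltages(inBand)[cyc])]
  pkOut <- t[cyc][which.max(voltages(out)[cyc])]
  expect_lt(abs(pkIn - pkOut), 1 / fs + 1e-12)

  slow <- ERGTrace(t, sin(2 * pi * 5 * t), onset = 0.05)
  att <- max(abs(voltages(extractOPs(slow))[t > 0.1 & t < 0.3]))
  expect_lt(20 * log10(att), -20)

  zero <- ERGTrace(t, rep(0, length(t)), onset = 0.05)
  expect_true(all(voltages(extractOPs(zero)) == 0))
  lowFs <- ERGTrace(seq(0, 0.4, by = 1 / 500), rep(0, 201), onset = 0.05)
  expect_error(extractOPs(lowFs), "Nyquist")
})

test_that("OP peak amplitudes recover the designed wavelet", {
  truth <- ERGTruth(150, 400, c(40, 30, 20, 10), 120, 0.077)
  tr <- generateERGTrace(truth, fs = 5000, noiseSd = 0)
  f <- ergFeatures(tr)
  expect_true(all(abs(f@opAmpsUv - truth@opAmps) / truth@opAmps <= 0.1))

  # linearity: doubling the OP component doubles the measured amplitudes
  tr2 <- generateERGTrace(ERGTruth(150, 400, 2 * c(40, 30, 20, 10), 120,
                                   0.077), fs = 5000, noiseSd = 0)
  f2 <- ergFeatures(tr2)
  expect_equal(f2@opAmpsUv / f@opAmpsUv, rep(2, 4), tolerance = 0.05)

  # zero trace: no peaks, NA padding with warning
  zero <- mkTrace(rep(0, 1000))
  expect_warning(ops <- opAmplitudes(extractOPs(zero), windowEndS = 0.1),
                 "padding")
  expect_true(all(is.na(ops)))
})

test_that("series analysis aggregates cells and preserves group ordering", {
  mkGroup <- function(scaleAmp, label, seeds) {
    lapply(seeds, function(s) generateERGTrace(
      ERGTruth(150 * scaleAmp, 400 * scaleAmp, c(40, 30, 20, 10) * scaleAmp),
      fs = 2000, noiseSd = 2, flash = 377.2, seed = s))
  }
  traces <- c(mkGroup(1, "WT", 1:2), mkGroup(0.5, "rd9", 3:4))
  tab <- analyzeERGSeries(traces, groups = rep(c("WT", "rd9"), each = 2))
  expect_equal(nrow(tab), 2L)
  wt <- tab[tab$group == "WT", ]; rd <- tab[tab$group == "rd9", ]
  expect_gt(wt$aAmpMean, rd$aAmpMean)
  expect_gt(wt$bAmpMean, rd$bAmpMean)

  # identical traces in a cell: SEM 0
  same <- list(generateERGTrace(ERGTruth(), noiseSd = 0),
               generateERGTrace(ERGTruth(), noiseSd = 0))
  tabS <- analyzeERGSeries(same)
  expect_equal(tabS$bAmpSem, 0)

  # amplitude ordering holds across the flash series in repeated draws
  set.seed(20)
  wins <- 0
  for (i in 1:20) {
    sW <- sample.int(1e6, 1); sR <- sample.int(1e6, 1)
    trW <- generateERGTrace(ERGTruth(150, 400, c(40, 30, 20, 10)),
                            fs = 2000, noiseSd = 10, seed = sW)
    trR <- generateERGTrace(ERGTruth(75, 220, c(20, 15, 10, 5),
                                     bPeakTime = 0.136),
                            fs = 2000, noiseSd = 10, seed = sR)
    wins <- wins + (ergFeatures(trW)@bAmpUv > ergFeatures(trR)@bAmpUv)
  }
  expect_gte(wins / 20, 0.95)
})

test_that("flash grids step 0.6 log units up to the brightest flash", {
  sg <- scotopicFlashGrid(); pg <- photopicFlashGrid()
  expect_equal(max(sg), 377.2)
  expect_equal(max(pg), 377.2)
  expect_equal(diff(log10(sg)), rep(0.6, length(sg) - 1))
  expect_equal(length(sg), 13L)
  expect_equal(length(pg), 8L)
})
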