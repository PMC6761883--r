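test_that("autofluorescence mask retains pixels at or below the red cutoff", {
  tl <- TwoChannelTile(matrix(20, 6, 6), matrix(0, 6, 6))
  expect_true(all(autofluorescenceMask(tl)))

  hot <- TwoChannelTile(matrix(20, 6, 6), matrix(255, 6, 6))
  expect_true(all(!autofluorescenceMask(hot)))
  expect_error(maskedMeanIntensity(hot, autofluorescenceMask(hot)),
               "empty retain")

  # synthetic tile: every punctum masked, masked fraction matches truth
  g <- generateRPETile(20, punctaCount = 40, punctaGreen = 200,
                       punctaRed = 50, noiseSd = 0, seed = 1)
  m <- autofluorescenceMask(g$tile)
  expect_true(all(!m[g$truth@punctaIdx]))
  expect_equal(1 - mean(m), length(g$truth@punctaIdx) / length(m))
})

test_that("masked mean matches closed-form mixture means", {
  flat <- TwoChannelTile(matrix(20, 10, 10), matrix(0, 10, 10))
  q <- maskedMeanIntensity(flat, autofluorescenceMask(flat))
  expect_equal(q@meanGreenMasked, 20)
  expect_equal(q@maskedFraction, 0)

  # 10% puncta at green 200 / red 50 on a green-20 background
  green <- matrix(20, 10, 10); red <- matrix(0, 10, 10)
  green[1:10] <- 200; red[1:10] <- 50
  tile <- TwoChannelTile(green, red)
  expect_equal(mean(green), 38)                      # unmasked mixture
  qm <- maskedMeanIntensity(tile, autofluorescenceMask(tile))
  expect_equal(qm@meanGreenMasked, 20)
  expect_equal(qm@maskedFraction, 0.1)

  # generator truth: masked mean equals the junction-mesh mixture mean
  g <- generateRPETile(17.14, punctaCount = 30, noiseSd = 0, seed = 2)
  tru <- g$truth
  n <- length(greenChannel(g$tile))
  keep <- setdiff(seq_len(n), tru@punctaIdx)
  closedForm <- 17.14 * length(setdiff(tru@junctionIdx, tru@punctaIdx)) /
    length(keep)
  qg <- maskedMeanIntensity(g$tile, autofluorescenceMask(g$tile))
  expect_equal(qg@meanGreenMasked, closedForm, tolerance = 1e-12)
})

test_that("masking properties: error reduction, cutoff monotonicity, no-op", {
  for (s in 1:10) {
    g <- generateRPETile(17.14, punctaCount = 40, noiseSd = 2, seed = s)
    tru <- g$truth
    n <- length(greenChannel(g$tile))
    keep <- setdiff(seq_len(n), tru@punctaIdx)
    trueMean <- 17.14 * length(setdiff(tru@junctionIdx, tru@punctaIdx)) /
      length(keep)
    masked <- maskedMeanIntensity(g$tile,
                                  autofluorescenceMask(g$tile))@meanGreenMasked
    unmasked <- mean(greenChannel(g$tile))
    expect_lte(abs(masked - trueMean), abs(unmasked - trueMean))
  }

  g <- generateRPETile(17.14, punctaCount = 40, noiseSd = 2, seed = 3)
  fracs <- vapply(c(2, 8, 30, 100), function(cut)
    1 - mean(autofluorescenceMask(g$tile, cut)), numeric(1))
  expect_true(all(diff(fracs) <= 0))

  # puncta below the cutoff: masking is a no-op
  gLow <- generateRPETile(20, punctaCount = 20, punctaRed = 5, noiseSd = 0,
                          seed = 4)
  m <- autofluorescenceMask(gLow$tile, 8)
  expect_true(all(m))
  expect_equal(maskedMeanIntensity(gLow$tile, m)@meanGreenMasked,
               mean(greenChannel(gLow$tile)))
})

test_that("group quantification reports fold change with its symmetries", {
  mk <- function(j, seeds) lapply(seeds, function(s)
    generateRPETile(j, punctaCount = 10, noiseSd = 0, width = 96,
                    height = 96, seed = s)$tile)
  tiles <- list(WT = mk(17.14, 1:3), rd9 = mk(5.2, 1:3))
  res <- quantifyGroup(tiles, reference = "WT", test = "rd9")
  # same mesh seeds: junction fraction identical, fold = 17.14 / 5.2
  expect_equal(res$foldChange, 17.14 / 5.2, tolerance = 0.02)
  expect_equal(res$foldChange, 3.3, tolerance = 0.05)

  same <- quantifyGroup(list(a = mk(10, 1:2), b = mk(10, 1:2)))
  expect_equal(same$foldChange, 1)

  swapped <- quantifyGroup(tiles, reference = "rd9", test = "WT")
  expect_equal(swapped$foldChange, 1 / res$foldChange)
  expect_error(quantifyGroup(list(a = mk(10, 1), b = mk(10, 1:2))),
               "at least 2")
})

test_that("saturated pixels are flagged rather than dropped", {
  green <- matrix(100, 8, 8); green[1:16] <- 255
  tl <- TwoChannelTile(green, matrix(0, 8, 8))
  expect_warning(q <- maskedMeanIntensity(tl, autofluorescenceMask(tl)),
                 "saturated")
  expect_equal(q@saturationFraction, 0.25)
  expect_equal(q@meanGreenMasked, mean(green))
})
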