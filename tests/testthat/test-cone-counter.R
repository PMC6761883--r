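test_that("binarization separates bimodal intensities and rejects blanks", {
  img <- matrix(c(20, 20, 20, 200, 200, 200), 2, 3)
  m <- binarizeField(img)
  expect_equal(m, img > 100, ignore_attr = TRUE)

  zero <- matrix(0, 5, 5)
  expect_error(binarizeField(zero, "otsu"), "degenerate")
  expect_true(all(!binarizeField(zero, "fixed", fixedThreshold = 10)))
  expect_error(binarizeField(img, "fixed"), "fixedThreshold")

  # on a synthetic mosaic the foreground component count before any
  # splitting equals placed blobs minus merged pairs (here: none)
  f <- generateConeMosaic(6000, 80, 80, seed = 4, noiseSd = 5,
                          touchingFraction = 0)
  mask <- filterSmall(binarizeField(f$image))
  expect_equal(max(EBImage::bwlabel(mask)), nrow(f$truth@positionsUm))
})

test_that("small-component filter removes debris below 2% of mean cone area", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE          # area 100
  m[20, 20] <- TRUE              # 1-px speck
  m[25:36, 25:37] <- TRUE        # area 156
  out <- filterSmall(m, meanConeAreaPx = 100, fraction = 0.02)
  expect_equal(attr(out, "nRemoved"), 1L)
  expect_equal(sum(out), 100 + 12 * 13)

  empty <- matrix(FALSE, 10, 10)
  expect_equal(sum(filterSmall(empty)), 0)

  # fraction below the smallest true component's relative area: no removal
  out2 <- filterSmall(m, meanConeAreaPx = 100, fraction = 0.009)
  expect_equal(attr(out2, "nRemoved"), 0L)
  expect_error(filterSmall(m, fraction = 0), "strictly between")
})

test_that("downsampling follows the rounding rule and preserves blobs", {
  m <- matrix(FALSE, 700, 524)
  expect_equal(dim(downsampleMask(m, 0.3)), c(210L, 157L))
  m[100:119, 100:119] <- TRUE    # 20-px blob
  ds <- downsampleMask(m, 0.3)
  expect_equal(max(splitTouching(ds)), 1L)
  expect_identical(downsampleMask(m, 1), m)
  expect_error(downsampleMask(m, 1.2), "0, 1")
})

test_that("watershed splitting matches the brute-force maxima oracle", {
  # isolated disk: one label
  m1 <- addDisk(matrix(FALSE, 40, 40), 20, 20, 6)
  expect_equal(max(splitTouching(m1)), 1L)
  expect_equal(bruteMaximaCount(m1), 1L)

  # two disks merged into one component: two labels
  m2 <- addDisk(addDisk(matrix(FALSE, 40, 50), 20, 20, 6), 20, 30, 6)
  expect_equal(max(EBImage::bwlabel(m2)), 1L)
  expect_equal(max(splitTouching(m2)), 2L)
  expect_equal(bruteMaximaCount(m2), 2L)

  expect_equal(max(splitTouching(matrix(FALSE, 10, 10))), 0L)

  # randomized fixtures, watershed vs oracle
  set.seed(10)
  for (rep in 1:6) {
    m <- matrix(FALSE, 80, 110)
    centers <- list()
    nBlob <- sample(3:6, 1)
    placed <- 0; tries <- 0
    while (placed < nBlob && tries < 5000) {
      tries <- tries + 1
      p <- c(runif(1, 10, 70), runif(1, 10, 88))
      if (all(vapply(centers, function(q) sum((q - p)^2) > 22^2, TRUE))) {
        centers[[length(centers) + 1]] <- p
        m <- addDisk(m, p[1], p[2], 6)
        placed <- placed + 1
        # half the blobs get a touching partner
        if (runif(1) < 0.5) {
          q <- p + c(0, 10)
          centers[[length(centers) + 1]] <- q
          m <- addDisk(m, q[1], q[2], 6)
          placed <- placed + 1
        }
      }
    }
    expect_equal(max(splitTouching(m)), bruteMaximaCount(m))
    expect_equal(max(splitTouching(m)), placed)
  }
})

test_that("border exclusion removes right/bottom components and is idempotent", {
  lab <- matrix(0L, 6, 8)
  lab[3, 6:8] <- 1L              # touches right border
  out <- excludeBorder(lab)
  expect_equal(max(out), 0L)
  expect_equal(attr(out, "nRemoved"), 1L)

  lab2 <- matrix(0L, 6, 8)
  lab2[1, 1:2] <- 1L             # top-left corner only: retained
  out2 <- excludeBorder(lab2)
  expect_equal(max(out2), 1L)
  expect_equal(attr(out2, "nRemoved"), 0L)

  lab3 <- matrix(0L, 10, 10)
  lab3[9:10, 3] <- 1L; lab3[2:3, 2] <- 2L; lab3[5, 9:10] <- 3L
  once <- excludeBorder(lab3)
  twice <- excludeBorder(once)
  expect_identical(as.vector(once), as.vector(twice))
  expect_equal(attr(twice, "nRemoved"), 0L)

  # generator oracle: flagged border blobs are exactly the removed ones
  for (s in 1:5) {
    f <- generateConeMosaic(12000, 111.9, 83.8, seed = s, noiseSd = 0,
                            touchingFraction = 0)
    lab <- EBImage::bwlabel(binarizeField(f$image))
    removed <- attr(excludeBorder(EBImage::imageData(lab)), "nRemoved")
    expect_equal(removed, f$truth@nExcludable)
  }
})

test_that("the full counting chain is exact on ideal input and robust to blanks", {
  f <- generateConeMosaic(12000, seed = 2, noiseSd = 0, touchingFraction = 0)
  res <- countField(f$image)
  expect_equal(nCones(res), f$truth@nTotal)
  expect_equal(nCones(res) + nRemovedBorder(res), length(componentAreasPx(res)))
  expect_equal(countParams(res)$areaFraction, 0.02)
  expect_equal(countParams(res)$downsampleFactor, 0.3)

  blank <- FieldImage(matrix(0, 120, 120), pxUm = 0.32)
  resB <- countField(blank)
  expect_equal(nCones(resB), 0L)
  expect_match(countParams(resB)$binarizeMethod, "fallback")
})

test_that("counts respond monotonically to the area-filter fraction", {
  f <- generateConeMosaic(12000, 111.9, 83.8, seed = 9, noiseSd = 5,
                          touchingFraction = 0.1)
  fracs <- c(0.01, 0.05, 0.2, 0.5)
  counts <- vapply(fracs, function(fr)
    nCones(countField(f$image, areaFraction = fr)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("manual-vs-automated comparison computes r, errors and accuracy", {
  cs <- compareCounts(c(100, 200), c(95, 210))
  expect_equal(cs@errors, c(0.05, -0.05))
  expect_equal(cs@accuracy, 0.95)

  same <- compareCounts(c(50, 60, 70), c(50, 60, 70))
  expect_equal(same@pearsonR, 1)
  expect_equal(same@accuracy, 1)

  expect_warning(cc <- compareCounts(c(100, 100, 100), c(90, 100, 110)),
                 "constant")
  expect_true(is.na(cc@pearsonR))
  expect_equal(cc@accuracy, 1 - mean(c(0.1, 0, 0.1)))

  expect_error(compareCounts(c(0, 10), c(1, 9)), "undefined")
  expect_error(compareCounts(1:3, 1:4), "equal length")
})
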