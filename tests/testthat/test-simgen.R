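test_that("simulators are deterministic and produce the stated geometry", {
  s1 <- simulateUnidirectional(uniSimConfig(), seed = 11, renderMovie = TRUE)
  s2 <- simulateUnidirectional(uniSimConfig(), seed = 11, renderMovie = TRUE)
  expect_identical(kymoPixels(kymograph(s1)), kymoPixels(kymograph(s2)))
  expect_identical(s1@tracks, s2@tracks)
  expect_identical(s1@movie, s2@movie)
  expect_equal(dim(kymoPixels(kymograph(s1))), c(300L, 300L))
  expect_equal(dim(s1@movie), c(20, 300, 300))
  s3 <- simulateUnidirectional(uniSimConfig(), seed = 12, renderMovie = FALSE)
  expect_false(identical(kymoPixels(kymograph(s1)), kymoPixels(kymograph(s3))))

  b <- simulateBidirectional(biSimConfig(), seed = 11, renderMovie = FALSE)
  expect_lte(nTracks(groundTruth(b)), 15)
  expect_true("moving" %in% names(b@tracks))
})

test_that("an empty simulation yields pure noise with flagged SNR", {
  s <- simulateUnidirectional(tinyUniCfg(nPerDirection = 0L), seed = 1,
                              renderMovie = FALSE)
  expect_equal(nTracks(groundTruth(s)), 0)
  expect_true(is.na(measuredSNR(s)))
})

test_that("a noise-free constant-velocity particle renders on its line", {
  tr <- data.frame(id = 1L, frame = 0:29, position = 10 + 2 * (0:29),
                   visible = TRUE, amplitude = 1, psf = 4)
  out <- renderTracks(tr, nFrames = 30, pathLength = 80, noiseSigma = 0)
  am <- apply(out$kymograph, 1, which.max) - 1L
  expect_equal(am, round(10 + 2 * (0:29)))
})

test_that("rendering obeys the trivial limits", {
  out <- renderTracks(data.frame(id = integer(), frame = integer(),
                                 position = numeric(), visible = logical(),
                                 amplitude = numeric(), psf = numeric()),
                      nFrames = 10, pathLength = 10, noiseSigma = 0)
  expect_true(all(out$kymograph == 1))  # constant baseline
  # a stationary particle gives the same column profile every frame
  tr <- data.frame(id = 1L, frame = 0:9, position = 20, visible = TRUE,
                   amplitude = 1, psf = 4)
  k <- renderTracks(tr, 10, 40, noiseSigma = 0)$kymograph
  for (f in 2:10) expect_equal(k[f, ], k[1, ])
  sg <- 4 / 2.355
  expect_equal(k[1, 21], 2, tolerance = 1e-12)          # baseline + peak
  expect_equal(k[1, 24], 1 + exp(-9 / (2 * sg^2)), tolerance = 1e-9)
})

test_that("gap assignment clips, stays interior and matches the clipped-exponential mean", {
  tr <- data.frame(frame = 0:99, position = 0:99)
  same <- assignGaps(tr, gapRate = 0, gapMeanLen = 2, maxGapLen = 6)
  expect_true(all(same$visible))

  set.seed(42)
  lens <- c()
  firstLast <- TRUE
  for (i in 1:500) {
    # low rate so gaps rarely collide (collisions discard the longer draw
    # and would bias the empirical mean)
    g <- assignGaps(tr, gapRate = 0.02, gapMeanLen = 2, maxGapLen = 6)
    r <- rle(!g$visible)
    lens <- c(lens, r$lengths[r$values])
    firstLast <- firstLast && g$visible[1] && g$visible[100]
  }
  expect_true(firstLast)
  expect_true(all(lens >= 1 & lens <= 6))
  # oracle: mean of ceil(Exp(mean 2)) clipped at 6, by direct summation
  pk <- exp(-(0:5) / 2) - exp(-(1:6) / 2)
  pk[6] <- pk[6] + exp(-6 / 2)
  oracleMean <- sum((1:6) * pk)
  expect_equal(mean(lens), oracleMean, tolerance = 0.06)
})

test_that("ground-truth tracks respect the velocity bound and gap clip", {
  steps <- 0L
  for (i in 1:8) {
    b <- simulateBidirectional(biSimConfig(), seed = 100 + i,
                               renderMovie = FALSE)
    for (tr in split(b@tracks, b@tracks$id)) {
      d <- abs(diff(tr$position))
      steps <- steps + length(d)
      expect_lte(max(d), b@config$vMax + 1.5 + 1e-9)
    }
    g <- gapTable(b)
    if (nrow(g)) expect_lte(max(g$len), b@config$maxGapLen)
  }
  expect_gt(steps, 10000)
})

test_that("no surviving track is fully occluded by another", {
  for (i in 1:4) {
    s <- simulateBidirectional(tinyBiCfg(nTracks = 12L), seed = 50 + i,
                               renderMovie = FALSE)
    per <- split(s@tracks, s@tracks$id)
    for (a in seq_along(per)) for (b in seq_along(per)) {
      if (a == b) next
      keyA <- paste(per[[a]]$frame, round(per[[a]]$position))
      keyB <- paste(per[[b]]$frame, round(per[[b]]$position))
      if (length(keyA) <= length(keyB))
        expect_false(all(keyA %in% keyB))
    }
  }
})

test_that("SNR measurement matches its definition and rejects degenerate masks", {
  img <- matrix(1, 4, 4)
  img[1, ] <- 2
  expect_equal(measureSNR(img, img > 1), 2)
  expect_equal(measureSNR(matrix(5, 3, 3),
                          matrix(c(TRUE, rep(FALSE, 8)), 3, 3)), 1)
  expect_error(measureSNR(img, matrix(FALSE, 4, 4)), "undefined")
  expect_error(measureSNR(img, matrix(TRUE, 4, 4)), "undefined")
})

test_that("bidirectional degenerate limits produce straight or piecewise-straight tracks", {
  cfg <- tinyBiCfg(nTracks = 6L, velocityNoiseRange = c(0, 0),
                   switchProbRange = c(0, 0), flipProbRange = c(0, 0))
  s <- simulateBidirectional(cfg, seed = 3, renderMovie = FALSE)
  for (tr in split(s@tracks, s@tracks$id)) {
    if (nrow(tr) < 3) next
    d <- diff(tr$position)
    expect_lt(diff(range(d)), 1e-9)  # constant slope
  }
  # flips only: slopes alternate between +v and -v
  cfg2 <- tinyBiCfg(nTracks = 6L, nFrames = 200L, pathLength = 200L,
                    velocityNoiseRange = c(0, 0),
                    switchProbRange = c(0, 0), flipProbRange = c(0.1, 0.1))
  s2 <- simulateBidirectional(cfg2, seed = 4, renderMovie = FALSE)
  sawFlip <- FALSE
  for (tr in split(s2@tracks, s2@tracks$id)) {
    if (nrow(tr) < 3) next
    d <- diff(tr$position)
    d <- d[tr$moving[-1]]            # displacements while moving
    d <- d[abs(d) > 1e-12]
    if (!length(d)) next
    expect_lt(diff(range(abs(d))), 1e-9)  # one speed magnitude
    if (length(unique(sign(d))) == 2) sawFlip <- TRUE
  }
  expect_true(sawFlip)
})
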