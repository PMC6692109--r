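test_that("kymograph extraction reproduces known movies", {
  # constant movie -> constant kymograph
  mov <- array(3, dim = c(10, 40, 6))
  p <- pathSpec(rbind(c(4.5, 0), c(4.5, 39)), width = 3)
  k <- extractKymograph(mov, p)
  expect_true(all(abs(kymoPixels(k) - 3) < 1e-12))
  expect_equal(nrow(kymoPixels(k)), 6)

  # single bright moving pixel, width 1: one bright pixel per frame
  mov2 <- array(0, dim = c(10, 40, 5))
  for (f in 1:5) mov2[5, 10 + 2 * f, f] <- 7  # 0-based position 9 + 2f
  k2 <- kymoPixels(extractKymograph(mov2, pathSpec(rbind(c(4, 0), c(4, 39)),
                                                   width = 1)))
  for (f in 1:5) {
    expect_equal(sum(k2[f, ] > 0), 1)
    expect_equal(which.max(k2[f, ]) - 1L, 9L + 2L * f)
  }

  # linearity of the mean aggregator
  set.seed(1)
  mov3 <- array(runif(10 * 40 * 4), dim = c(10, 40, 4))
  pm <- pathSpec(rbind(c(4, 0), c(4, 39)), width = 5)
  k1 <- kymoPixels(extractKymograph(mov3, pm, aggregator = "mean"))
  k5 <- kymoPixels(extractKymograph(5 * mov3, pm, aggregator = "mean"))
  expect_equal(k5, 5 * k1, tolerance = 1e-12)

  expect_error(extractKymograph(mov3, pathSpec(rbind(c(0, 0), c(50, 39)))),
               "bounds")
})

test_that("kymographs extracted from simulated movies track the ground truth", {
  s <- simulateUnidirectional(tinyUniCfg(nPerDirection = 2L,
                                         amplitude = 2, targetSNR = 2.5),
                              seed = 6, renderMovie = TRUE)
  mid <- (dim(s@movie)[1] - 1) / 2
  k <- extractKymograph(s@movie, pathSpec(rbind(c(mid, 0),
                                                c(mid, 79)), width = 5))
  px <- kymoPixels(k)
  vis <- s@tracks[s@tracks$visible, ]
  # in every frame with signal, the brightest kymograph pixel sits on
  # one of the visible ground-truth particles (within 1 px)
  frames <- sort(unique(vis$frame))
  off <- vapply(frames, function(f) {
    am <- which.max(px[f + 1L, ]) - 1L
    min(abs(vis$position[vis$frame == f] - am))
  }, numeric(1))
  expect_lt(median(off), 1.01)
  expect_lte(mean(off <= 1.5), 1)
  expect_gte(mean(off <= 1.5), 0.9)
})

test_that("track CSVs round-trip and outputs are written deterministically", {
  tr <- kymoTracks(data.frame(id = c(1, 1, 1, 2, 2, 2),
                              frame = c(0:2, 4:6),
                              position = c(1.5, 2.25, 3, 10, 10, 10)))
  dir <- withr::local_tempdir()
  files <- writeOutputs(tr, Kymograph(matrix(1, 10, 15)), dir, mode = "bi")
  expect_true(all(file.exists(files)))
  back <- readTracksCSV(files["tracks"])
  expect_equal(as.data.frame(back)$position, as.data.frame(tr)$position)
  expect_equal(nrow(as.data.frame(back)), 6)  # row count = sum of lengths

  # empty track list: header-only CSV
  files2 <- writeOutputs(kymoTracks(), Kymograph(matrix(1, 10, 15)),
                         dir, prefix = "empty")
  expect_equal(nrow(read.csv(files2["tracks"])), 0)

  # identical color seed -> identical overlay bytes
  f1 <- writeOutputs(tr, Kymograph(matrix(1, 10, 15)), dir, prefix = "a",
                     colorSeed = 7)
  f2 <- writeOutputs(tr, Kymograph(matrix(1, 10, 15)), dir, prefix = "b",
                     colorSeed = 7)
  expect_identical(readBin(f1["overlay"], "raw", 1e6),
                   readBin(f2["overlay"], "raw", 1e6))
})

test_that("the overlay colours exactly the 3x3-dilated track support", {
  tr <- kymoTracks(data.frame(id = 1, frame = 2:6, position = 2:6))
  ov <- trackOverlay(tr, c(10, 10), colorSeed = 1)
  lit <- ov[, , 1] + ov[, , 2] + ov[, , 3] > 0
  # oracle: direct 3x3 dilation of the rounded track support
  m <- matrix(FALSE, 10, 10)
  m[cbind(3:7, 3:7)] <- TRUE
  dil <- matrix(FALSE, 10, 10)
  for (r in 1:10) for (c in 1:10) if (m[r, c])
    dil[max(1, r - 1):min(10, r + 1), max(1, c - 1):min(10, c + 1)] <- TRUE
  expect_identical(lit, dil)
})

test_that("movies and kymographs survive a TIFF round trip", {
  s <- simulateUnidirectional(tinyUniCfg(nPerDirection = 1L), seed = 2,
                              renderMovie = TRUE)
  dir <- withr::local_tempdir()
  writeMovieTiff(s@movie, file.path(dir, "m.tif"))
  mov <- readMovieTiff(file.path(dir, "m.tif"))
  expect_equal(dim(mov), dim(s@movie))
  expect_equal(mov, s@movie / max(s@movie), tolerance = 1e-6)  # stored scaled
  writeKymographTiff(kymograph(s), file.path(dir, "k.tif"))
  k <- readKymographTiff(file.path(dir, "k.tif"))
  px <- kymoPixels(kymograph(s))
  expect_equal(kymoPixels(k), px / max(px), tolerance = 1e-6)
})
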