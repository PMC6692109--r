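test_that("recall and precision follow their definitions on constructed cases", {
  gt <- lineTrack(1, 0:9, 10, 1)
  expect_equal(unname(trackRecall(gt, gt)), 1)
  expect_equal(unname(trackPrecision(gt, gt)), 1)
  empty <- data.frame(id = integer(), frame = integer(),
                      position = numeric())
  expect_equal(unname(trackRecall(gt, empty)), 0)

  # split prediction: best single fragment gives recall 0.5
  frag <- rbind(lineTrack(1, 0:4, 10, 1), lineTrack(2, 5:9, 15, 1))
  expect_equal(unname(trackRecall(gt, frag)), 0.5)

  # prediction extending 5 frames beyond a 5-frame ground truth: 0.5
  gt5 <- lineTrack(1, 0:4, 10, 1)
  long <- lineTrack(1, 0:9, 10, 1)
  expect_equal(unname(trackPrecision(gt5, long)), 0.5)

  # hallucinated track far away scores 0
  far <- lineTrack(9, 0:9, 200, 0)
  expect_equal(unname(trackPrecision(gt, far)), 0)

  expect_equal(trackF1(1, 1), 1)
  expect_equal(trackF1(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(trackF1(0.9, 0.4), 0.6)
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(71)
  for (case in 1:60) {
    nFrames <- sample(10:50, 1)
    gt <- randomTrackSet(sample(1:5, 1), nFrames, 60, NULL)
    pred <- randomTrackSet(sample(0:5, 1), nFrames, 60, NULL)
    if (!nrow(pred)) pred <- pred[0, ]
    expect_equal(unname(trackRecall(gt, pred)), oracleRecall(gt, pred))
    if (nrow(pred))
      expect_equal(unname(trackPrecision(gt, pred)),
                   oraclePrecision(gt, pred))
  }
})

test_that("gap scoring requires every gap frame to be covered", {
  gt <- lineTrack(1, 0:19, 5, 1)
  gaps <- data.frame(id = 1L, start = 8L, len = 3L)
  expect_equal(gapScore(gaps, gt, gt), 1)

  # prediction broken exactly at the gap: unresolved
  broken <- rbind(lineTrack(1, 0:7, 5, 1), lineTrack(2, 11:19, 16, 1))
  expect_equal(gapScore(gaps, gt, broken), 0)

  # covering all but one gap frame is still unresolved
  almost <- rbind(lineTrack(1, 0:8, 5, 1), lineTrack(2, 10:19, 15, 1))
  expect_equal(gapScore(gaps, gt, almost), 0)

  noGaps <- gaps[0, ]
  expect_true(is.na(gapScore(noGaps, gt, gt)))
})

test_that("crossing scoring resolves complete predictions and fails truncated ones", {
  dims <- c(40, 40)
  a <- lineTrack(1, 0:39, 0, 1)
  b <- lineTrack(2, 0:38, 38, -1)  # crosses a exactly at (19, 19)
  gt <- rbind(a, b)
  expect_equal(crossingScore(gt, gt, dims), 1)

  # predictions that terminate at the crossing resolve nothing
  cut <- rbind(lineTrack(1, 0:19, 0, 1), lineTrack(2, 0:19, 38, -1),
               lineTrack(3, 20:39, 20, 1), lineTrack(4, 20:38, 18, -1))
  expect_equal(crossingScore(gt, cut, dims), 0)

  # parallel tracks have no crossings
  par <- rbind(lineTrack(1, 0:39, 0, 0.5), lineTrack(2, 0:39, 30, 0.5))
  expect_true(is.na(crossingScore(par, par, dims)))
})

test_that("recall never decreases when two fragments of a track merge", {
  set.seed(17)
  for (i in 1:20) {
    gt <- randomTrackSet(1, 30, 50, NULL)
    n <- nrow(gt)
    cutAt <- sample(2:(n - 1), 1)
    frag <- gt
    frag$id[seq_len(n) > cutAt] <- 2L
    merged <- gt
    expect_gte(unname(trackRecall(gt, merged)) + 1e-12,
               unname(trackRecall(gt, frag)))
  }
})

test_that("metrics are invariant under a global translation", {
  set.seed(23)
  gt <- randomTrackSet(3, 30, 50, NULL)
  pred <- randomTrackSet(3, 30, 50, NULL)
  shift <- function(df, dx) transform(df, position = position + dx)
  expect_equal(trackRecall(gt, pred), trackRecall(shift(gt, 7),
                                                  shift(pred, 7)))
  expect_equal(trackPrecision(gt, pred), trackPrecision(shift(gt, 7),
                                                        shift(pred, 7)))
})

test_that("the benchmark driver scores a perfect oracle at 1 and an empty engine at 0", {
  samples <- lapply(1:3, function(i)
    simulateBidirectional(tinyBiCfg(nTracks = 6L), seed = 300 + i,
                          renderMovie = FALSE))
  rep <- benchmarkSet(samples, function(s) groundTruth(s))
  m <- reportMedians(rep)
  expect_equal(unname(m["f1"]), 1)
  expect_equal(unname(m["gapScore"]), 1)
  if (!is.na(m["crossingScore"]))
    expect_equal(unname(m["crossingScore"]), 1)

  repEmpty <- benchmarkSet(samples, function(s) kymoTracks())
  expect_equal(unname(reportMedians(repEmpty)["f1"]), 0)
  expect_s4_class(rep, "BenchmarkReport")
  expect_equal(nrow(perKymograph(rep)), 3)
})
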