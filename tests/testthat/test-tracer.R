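test_that("binarization counts pixels exactly and is monotone", {
  m <- matrix(c(0.25, 0.9, 0.1, 0.05, 0.2, 0.5, 0.19, 0.19, 0, 0, 0.01,
                0.15, 0.3, 0.02, 0.18, 0.12), 4, 4)
  expect_equal(sum(binarizeMap(m, 0.2)), 5)
  expect_equal(sum(binarizeMap(matrix(0, 5, 5), 0.3)), 0)
  set.seed(3)
  r <- matrix(runif(400), 20)
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(th) sum(binarizeMap(r, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("thinning preserves thin structures and prunes short spurs", {
  d <- matrix(0L, 12, 12)
  d[cbind(2:10, 2:10)] <- 1L
  expect_identical(thinPrune(d, 3), d)  # 1-px diagonal untouched

  band <- matrix(0L, 20, 20)
  band[3:18, 9:11] <- 1L
  sk <- thinPrune(band, 3)
  rows <- rowSums(sk)
  expect_true(all(rows <= 1))          # 1-px spine
  expect_gte(sum(rows == 1), 12)       # covering almost the full band

  # a 2-px spur off a long vertical line disappears; the line stays
  sp <- matrix(0L, 15, 15)
  sp[2:14, 7] <- 1L
  sp[8, 8] <- 1L
  sp[9, 9] <- 1L
  pr <- thinPrune(sp, 3)
  expect_equal(pr[8, 8] + pr[9, 9], 0)
  expect_true(all(pr[2:14, 7] == 1))
})

test_that("end trimming removes only horizontal track ends", {
  v <- matrix(0L, 10, 10)
  v[2:9, 5] <- 1L
  expect_identical(trimEnds(v), v)
  expect_identical(trimEnds(matrix(0L, 5, 5)), matrix(0L, 5, 5))

  # an L with a 3-px horizontal foot is shortened until the end pixel
  # has a neighbour in a different row (the corner-adjacent pixel stays:
  # it touches the previous row diagonally)
  L <- matrix(0L, 5, 5)
  L[1:3, 2] <- 1L
  L[3, 3:5] <- 1L
  tr <- trimEnds(L)
  expect_equal(sum(tr[3, 4:5]), 0)
  expect_true(all(tr[1:3, 2] == 1))
})

test_that("seed detection matches a direct hit-miss correlation", {
  v <- matrix(0L, 10, 10)
  v[1:10, 6] <- 1L
  s <- findSeeds(v)
  expect_equal(nrow(s), 1)
  expect_equal(s[1, ], c(0L, 5L))

  two <- matrix(0L, 20, 20)
  two[3:12, 4] <- 1L
  two[cbind(7:16, 10:19)] <- 1L
  s2 <- findSeeds(two)
  expect_equal(nrow(s2), 2)
  expect_true(all(paste(s2[, 1], s2[, 2]) %in% c("2 3", "6 9")))

  expect_equal(nrow(findSeeds(matrix(0L, 5, 5))), 0)

  set.seed(9)
  for (i in 1:5) {
    sk <- matrix(as.integer(runif(15 * 15) < 0.2), 15, 15)
    got <- findSeeds(sk)
    want <- oracleSeeds(sk)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("track following walks lines and defers branches to the decider", {
  line <- matrix(0L, 20, 20)
  line[cbind(1:15, 3:17)] <- 1L
  branchCalls <- 0
  rt <- followTrack(c(0, 2), line, line * 0, function(k, s, ch) {
    # the decider is consulted once at the natural end (0 candidates);
    # a branch consultation would arrive with the chain incomplete
    if (nrow(ch) < 15) branchCalls <<- branchCalls + 1
    NULL
  })
  expect_equal(nrow(rt$chain), 15)
  expect_equal(branchCalls, 0)
  expect_length(rt$confidences, 0)

  # X crossing: stub decider picks the straight-through arm
  X <- matrix(0L, 21, 21)
  X[cbind(1:21, 1:21)] <- 1L
  X[cbind(1:21, 21:1)] <- 1L
  straight <- function(k, s, ch) {
    end <- ch[nrow(ch), ]
    if (end[1] >= 20) return(NULL)  # reached the bottom: terminate
    fut <- cbind(end[1] + 1:5, end[2] + 1:5)
    list(component = fut, confidence = 0.8)
  }
  rt2 <- followTrack(c(0, 0), X, X * 0, straight)
  expect_equal(rt2$confidences, 0.8)
  expect_true(all(rt2$chain[, 1] == rt2$chain[, 2]))  # stayed on the diagonal
  expect_equal(nrow(rt2$chain), 21)

  # a 2-px component is refused and the track terminates at the branch
  short <- function(k, s, ch) {
    end <- ch[nrow(ch), ]
    list(component = cbind(end[1] + 1:2, end[2] + 1:2), confidence = 0.9)
  }
  rt3 <- followTrack(c(0, 0), X, X * 0, short)
  expect_lt(nrow(rt3$chain), 15)
  expect_length(rt3$confidences, 0)
})

test_that("consolidation removes subsets and short tracks and assigns overlaps", {
  mk <- function(rows, cols, confs = numeric()) {
    list(chain = cbind(as.integer(rows), as.integer(cols)),
         confidences = confs)
  }
  # identical raw tracks: one survives
  out <- consolidateTracks(list(mk(0:9, 0:9), mk(0:9, 0:9)))
  expect_equal(nTracks(out), 1)

  # 4-px track removed by the length filter
  expect_equal(nTracks(consolidateTracks(list(mk(0:3, 0:3)))), 0)

  # a 12-frame shared run goes to the higher-confidence track
  shared <- mk(c(0:19), c(rep(5, 20)), confs = 0.9)
  loser <- mk(c(4:19, 20:24), c(rep(5, 16), 6:10), confs = 0.6)
  out2 <- consolidateTracks(list(shared, loser))
  pts <- as.data.frame(out2)
  winner <- pts[pts$position == 5 & pts$frame %in% 4:15, ]
  expect_equal(nrow(winner), 12)
  expect_equal(length(unique(winner$id)), 1)
  byId <- split(pts, pts$id)
  lens <- vapply(byId, nrow, integer(1))
  # the loser keeps only its non-shared tail
  expect_setequal(unname(lens), c(5, 20))

  # idempotence on integer-position tracks: a second pass changes nothing
  out3 <- consolidateTracks(list(mk(0:9, 0:9), mk(3:14, rep(2, 12))))
  again <- consolidateTracks(lapply(trackList(out3), function(tr)
    list(chain = cbind(tr$frame, as.integer(round(tr$position))),
         confidences = numeric())))
  expect_equal(nTracks(again), nTracks(out3))
  expect_equal(as.data.frame(again)$position, as.data.frame(out3)$position)
})

test_that("unidirectional extraction turns clean maps into per-frame tracks", {
  expect_equal(nTracks(extractUnidirectionalTracks(matrix(0, 30, 30),
                                                   matrix(0, 30, 30))), 0)
  pos <- matrix(0, 40, 50)
  pos[cbind(3:30, 5:32)] <- 1
  pos[cbind(3:30, 15:42)] <- 1
  neg <- matrix(0, 40, 50)
  tr <- extractUnidirectionalTracks(pos, neg, 0.2)
  expect_equal(nTracks(tr), 2)
  for (t in trackList(tr))
    expect_equal(diff(t$position), rep(1, nrow(t) - 1), tolerance = 1e-9)

  # a 2-frame blip is discarded
  blip <- matrix(0, 30, 30)
  blip[3, 10] <- 1
  blip[4, 11] <- 1
  expect_equal(nTracks(extractUnidirectionalTracks(blip,
                                                   matrix(0, 30, 30))), 0)
})

test_that("pipeline routing respects forced modes and output contracts", {
  models <- list(class = buildModule("class", widthMultiplier = 1 / 32),
                 uniseg = buildModule("uniseg", widthMultiplier = 1 / 32),
                 biseg = buildModule("biseg", widthMultiplier = 1 / 32),
                 decision = buildModule("decision", widthMultiplier = 1 / 32))
  set.seed(4)
  kym <- matrix(runif(64 * 64), 64)
  outBi <- runPipeline(kym, models, mode = "bi")
  expect_equal(attr(outBi, "mode"), "bi")
  outUni <- runPipeline(kym, models, mode = "uni")
  expect_equal(attr(outUni, "mode"), "uni")
  outAuto <- runPipeline(kym, models, mode = "auto")
  expect_true(attr(outAuto, "mode") %in% c("uni", "bi"))
  for (out in list(outBi, outUni, outAuto)) {
    pts <- as.data.frame(out)
    if (!nrow(pts)) next
    expect_true(all(pts$frame >= 0 & pts$frame < 64))
    expect_true(all(pts$position >= 0 & pts$position <= 63))
    for (tr in trackList(out)) expect_false(anyDuplicated(tr$frame) > 0)
  }
})
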