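# Track-level benchmarking: recall, precision, F1 (geometric mean),
# gap-bridging fraction and crossing-resolution fraction, plus the
# set-level driver.

.track_points <- function(x) {
  if (is(x, "KymoTracks")) x@points else as.data.frame(x)
}

#' Track recall
#'
#' For each ground-truth track, the best single predicted track is the
#' one covering the largest fraction of its points; a ground-truth point
#' is covered when that prediction has a point at the same frame within
#' \code{tol} (3.2 px, two diagonal pixels). Recall is 1 for a fully
#' recovered track and 0 for a missed one; a ground-truth track split
#' into two predictions scores only the larger fragment.
#'
#' @param gt,pred \linkS4class{KymoTracks} or point tables in common
#'   coordinates.
#' @param tol positional tolerance in pixels.
#' @return named numeric vector, one recall per ground-truth track.
#' @export
trackRecall <- function(gt, pred, tol = 3.2) {
  gt <- .track_points(gt); pred <- .track_points(pred)
  gsplit <- split(gt, gt$id)
  psplit <- split(pred, pred$id)
  vapply(gsplit, function(g) {
    if (!length(psplit)) return(0)
    max(vapply(psplit, function(p) {
      m <- match(g$frame, p$frame)
      mean(!is.na(m) & abs(g$position - p$position[m]) <= tol, na.rm = FALSE)
    }, numeric(1)))
  }, numeric(1))
}

#' Track precision
#'
#' Symmetric to recall: each predicted track is matched to the
#' ground-truth track it overlaps most, and the overlapping fraction of
#' the prediction is returned (1 = prediction fully inside a ground
#' truth track, 0 = hallucinated).
#'
#' @inheritParams trackRecall
#' @return named numeric vector, one precision per predicted track.
#' @export
trackPrecision <- function(gt, pred, tol = 3.2) {
  gt <- .track_points(gt); pred <- .track_points(pred)
  gsplit <- split(gt, gt$id)
  psplit <- split(pred, pred$id)
  vapply(psplit, function(p) {
    if (!length(gsplit)) return(0)
    max(vapply(gsplit, function(g) {
      m <- match(p$frame, g$frame)
      mean(!is.na(m) & abs(p$position - g$position[m]) <= tol)
    }, numeric(1)))
  }, numeric(1))
}

#' Track F1 score
#'
#' Geometric mean of the average track recall and the average track
#' precision. With no predictions the precision term is 0; with no
#' ground truth the score is NA.
#'
#' @param recalls per-ground-truth recalls.
#' @param precisions per-prediction precisions.
#' @return scalar in [0, 1] (or NA).
#' @examples
#' trackF1(c(0.9, 0.9), c(0.4, 0.4))  # 0.6
#' @export
trackF1 <- function(recalls, precisions) {
  if (!length(recalls)) return(NA_real_)
  r <- mean(recalls)
  p <- if (length(precisions)) mean(precisions) else 0
  sqrt(r * p)
}

#' Gap-bridging score
#'
#' A gap is resolved iff every one of its frames has some predicted
#' point within \code{tol} (3 px) of the ground-truth position; if one
#' or more frames have no overlapping segment the gap is unresolved.
#'
#' @param gaps gap table (id, start, len) as from \code{\link{gapTable}}.
#' @param gt ground-truth tracks (all points, gaps included).
#' @param pred predicted tracks.
#' @param tol positional tolerance in pixels.
#' @return fraction of gaps resolved, or NA when there are no gaps.
#' @export
gapScore <- function(gaps, gt, pred, tol = 3) {
  if (!nrow(gaps)) return(NA_real_)
  gt <- .track_points(gt); pred <- .track_points(pred)
  resolved <- vapply(seq_len(nrow(gaps)), function(k) {
    g <- gaps[k, ]
    tr <- gt[gt$id == g$id, ]
    frames <- g$start + seq_len(g$len) - 1L
    all(vapply(frames, function(f) {
      gp <- tr$position[tr$frame == f]
      if (!length(gp)) return(FALSE)
      any(abs(pred$position[pred$frame == f] - gp) <= tol)
    }, logical(1)))
  }, logical(1))
  mean(resolved)
}

.render_dilated <- function(points, dims, brush = matrix(1, 3, 3)) {
  m <- .int_mat(.render_binary_tracks(points, dims))
  if (!is.null(brush)) m <- .int_mat(EBImage::dilate(m, brush))
  m
}

#' Crossing-resolution score
#'
#' Pairwise products of ground-truth track rasters give crossing dots;
#' the dots are dilated to radius-16 discs, and the disc's intersection
#' with each single-track raster is that track's cross segment. A
#' crossing is resolved for a track iff some single predicted track
#' (dilated once, 3 x 3) covers at least \code{coverFrac} (70 %) of the
#' cross segment.
#'
#' @param gt,pred tracks in common coordinates.
#' @param dims c(nFrames, pathLength) raster dimensions.
#' @param coverFrac required covered fraction.
#' @param dilateRadius disc radius for the crossing circles.
#' @return fraction of (crossing, track) instances resolved, or NA when
#'   the ground truth has no crossings.
#' @export
crossingScore <- function(gt, pred, dims, coverFrac = 0.7,
                          dilateRadius = 16L) {
  gt <- .track_points(gt); pred <- .track_points(pred)
  gsplit <- split(gt, gt$id)
  if (length(gsplit) < 2) return(NA_real_)
  rasters <- lapply(gsplit, .render_dilated, dims = dims, brush = NULL)
  disc <- .int_mat(EBImage::makeBrush(2L * dilateRadius + 1L, "disc"))
  predR <- lapply(split(pred, pred$id), .render_dilated, dims = dims)
  ids <- seq_along(rasters)
  total <- 0L; resolved <- 0L
  for (a in ids) for (b in ids) {
    if (a >= b) next
    dots <- rasters[[a]] * rasters[[b]]
    if (!any(dots > 0)) next
    circ <- .int_mat(EBImage::dilate(dots, disc))
    lab <- cpp_label8(circ)
    for (l in seq_len(max(lab))) {
      inCirc <- lab == l
      for (tk in c(a, b)) {
        seg <- which(rasters[[tk]] > 0 & inCirc)
        if (!length(seg)) next
        total <- total + 1L
        ok <- any(vapply(predR, function(pr)
          sum(pr[seg] > 0) / length(seg) >= coverFrac, logical(1)))
        if (length(predR) && ok) resolved <- resolved + 1L
      }
    }
  }
  if (total == 0L) return(NA_real_)
  resolved / total
}

#' Discard tracks below the quantification filters
#'
#' Tracks smaller than \code{minPx} points or spanning fewer than
#' \code{minFrames} frames are removed before scoring.
#'
#' @param tracks a \linkS4class{KymoTracks}.
#' @param minPx,minFrames filters.
#' @return filtered \linkS4class{KymoTracks}.
#' @export
filterShortTracks <- function(tracks, minPx = 3L, minFrames = 3L) {
  pts <- .track_points(tracks)
  if (!nrow(pts)) return(kymoTracks())
  keep <- vapply(split(pts, pts$id), function(tr)
    nrow(tr) >= minPx && diff(range(tr$frame)) + 1L >= minFrames,
    logical(1))
  ids <- names(keep)[keep]
  kymoTracks(pts[as.character(pts$id) %in% ids, , drop = FALSE])
}

#' Benchmark an engine over a set of synthetic samples
#'
#' Runs \code{engine(sample)} on each kymograph, applies the shared
#' pre-filter (tracks at least 3 points and 3 frames) to predictions and
#' ground truth, and aggregates per-kymograph recall, precision, F1, gap
#' and crossing scores plus set medians (undefined scores are excluded
#' from medians, not coerced).
#'
#' @param samples list of \linkS4class{SyntheticSample}s.
#' @param engine function(sample) returning a \linkS4class{KymoTracks}.
#' @return a \linkS4class{BenchmarkReport}.
#' @export
benchmarkSet <- function(samples, engine) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    dims <- dim(kymoPixels(s@kymograph))
    gt <- filterShortTracks(groundTruth(s))
    pred <- filterShortTracks(engine(s))
    rec <- trackRecall(gt, pred)
    prec <- trackPrecision(gt, pred)
    gaps <- gapTable(s)
    gaps <- gaps[as.character(gaps$id) %in% as.character(trackIds(gt)), ,
                 drop = FALSE]
    data.frame(sample = i,
               recall = if (length(rec)) mean(rec) else NA_real_,
               precision = if (length(prec)) mean(prec) else 0,
               f1 = trackF1(rec, prec),
               gapScore = gapScore(gaps, gt, pred),
               crossingScore = crossingScore(gt, pred, dims),
               nTracks = nTracks(pred), nGaps = nrow(gaps))
  })
  per <- do.call(rbind, rows)
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  new("BenchmarkReport", perKymograph = per,
      medians = c(recall = med(per$recall), precision = med(per$precision),
                  f1 = med(per$f1), gapScore = med(per$gapScore),
                  crossingScore = med(per$crossingScore)))
}
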