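# Derived kinematic quantities per track and per kymograph: mean
# frame-to-frame speed, summed absolute displacement, travel time,
# directionality, pausing and reversals.

#' Summarise one track
#'
#' Speeds are absolute frame-to-frame displacements (per frame, so
#' entries separated by a gap contribute their average rate).
#' Directionality: for unidirectional tracks, the sign of the end-to-end
#' displacement. For bidirectional tracks the displacement series is cut
#' into contiguous, non-overlapping, left-aligned segments of up to five
#' frames; a segment scores +1 when all its displacements exceed
#' \code{pauseTol}, -1 when all are below \code{-pauseTol}, and 0
#' otherwise; track directionality is the sign of the summed segment
#' scores, the pause time is the number of segments whose displacements
#' are all within \code{pauseTol} of zero, and a track reverses when it
#' has segments of both signs.
#'
#' @param track data.frame with columns frame, position (or a single-id
#'   \linkS4class{KymoTracks}).
#' @param mode "uni" or "bi".
#' @param pauseTol zero-displacement tolerance in px/frame (positions
#'   from row averaging are fractional, so exact zeros are rare).
#' @return one-row data.frame: meanSpeed, totalDisplacement, travelTime,
#'   directionality, pauseTime, reversing.
#' @examples
#' summarizeTrack(data.frame(frame = 0:9, position = 0:9), mode = "uni")
#' @export
summarizeTrack <- function(track, mode = c("uni", "bi"), pauseTol = 0.5) {
  mode <- match.arg(mode)
  tr <- .track_points(if (is(track, "KymoTracks")) track else
    cbind(id = 1L, as.data.frame(track)))
  tr <- tr[order(tr$frame), ]
  n <- nrow(tr)
  if (n < 2)
    return(data.frame(meanSpeed = 0, totalDisplacement = 0,
                      travelTime = max(n, 1), directionality = 0,
                      pauseTime = 0, reversing = FALSE))
  d <- diff(tr$position) / diff(tr$frame)
  out <- data.frame(meanSpeed = mean(abs(d)),
                    totalDisplacement = sum(abs(diff(tr$position))),
                    travelTime = n, directionality = 0, pauseTime = 0,
                    reversing = FALSE)
  if (mode == "uni") {
    out$directionality <- sign(tr$position[n] - tr$position[1])
    return(out)
  }
  segId <- (seq_len(n) - 1) %/% 5          # frames 0-4, 5-9, ... per segment
  scores <- integer(0); pauses <- 0L
  for (s in unique(segId)) {
    idx <- which(segId == s)
    dIdx <- idx[idx < max(idx)]            # displacements inside the segment
    if (!length(dIdx)) next
    ds <- d[dIdx]
    sc <- if (all(ds > pauseTol)) 1L else if (all(ds < -pauseTol)) -1L else 0L
    scores <- c(scores, sc)
    if (all(abs(ds) <= pauseTol)) pauses <- pauses + 1L
  }
  out$directionality <- sign(sum(scores))
  out$pauseTime <- pauses
  out$reversing <- any(scores == 1L) && any(scores == -1L)
  out
}

#' Summarise all tracks of a kymograph
#'
#' Averages the per-track quantities and adds the particle count and the
#' percentage of reversing tracks (tracks with segments in both
#' directions divided by all tracks).
#'
#' @param tracks a \linkS4class{KymoTracks} or point table.
#' @param mode "uni" or "bi".
#' @param pauseTol see \code{\link{summarizeTrack}}.
#' @param perTrack also return the per-track rows (the aggregate row has
#'   id NA).
#' @return a data.frame.
#' @export
summarizeKymograph <- function(tracks, mode = c("uni", "bi"),
                               pauseTol = 0.5, perTrack = FALSE) {
  mode <- match.arg(mode)
  pts <- .track_points(tracks)
  if (!nrow(pts)) {
    agg <- data.frame(id = NA, meanSpeed = NA, totalDisplacement = NA,
                      travelTime = NA, directionality = NA, pauseTime = NA,
                      reversalPct = NA, nParticles = 0)
    return(agg)
  }
  per <- do.call(rbind, lapply(split(pts, pts$id), function(tr)
    cbind(id = tr$id[1],
          summarizeTrack(tr[, c("frame", "position")], mode, pauseTol))))
  agg <- data.frame(id = NA,
                    meanSpeed = mean(per$meanSpeed),
                    totalDisplacement = mean(per$totalDisplacement),
                    travelTime = mean(per$travelTime),
                    directionality = mean(per$directionality),
                    pauseTime = mean(per$pauseTime),
                    reversalPct = 100 * mean(per$reversing),
                    nParticles = nrow(per))
  if (!perTrack) return(agg)
  per$reversalPct <- 100 * as.numeric(per$reversing)
  per$nParticles <- 1
  per$reversing <- NULL
  rbind(per[, names(agg)], agg)
}
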