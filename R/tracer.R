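# Skeleton tracing: binarize a trackness map, thin it to 1-px width,
# prune short spurs, trim horizontal track ends, detect seeds with a
# hit-miss transform, follow each seed forward in time resolving branch
# points with a pluggable decision function, and consolidate the raw
# pixel chains into per-frame tracks.

#' Binarize a trackness map
#'
#' @param map matrix with values in [0, 1].
#' @param threshold a pixel is foreground iff its trackness >= threshold.
#'   The shipped default is 0.2; useful values generally lie in 0.1-0.3.
#' @return integer 0/1 matrix.
#' @export
binarizeMap <- function(map, threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1)
  .int_mat(matrix(as.integer(map >= threshold), nrow(map), ncol(map)))
}

#' Thin to a 1-px skeleton and prune short spurs
#'
#' Iterative (Zhang-Suen) thinning followed by deletion of spur branches
#' shorter than \code{minBranch} pixels.
#'
#' @param bin binary matrix.
#' @param minBranch minimum surviving branch length (px).
#' @return binary skeleton matrix.
#' @export
thinPrune <- function(bin, minBranch = 3L) {
  cpp_prune(cpp_thin(.int_mat(bin)), as.integer(minBranch))
}

#' Trim horizontal track ends
#'
#' Iteratively removes endpoint pixels whose only neighbour lies in the
#' same row, so that every track end has its neighbour in a different
#' row (time step). Required before seed detection.
#'
#' @param skel binary skeleton matrix.
#' @return trimmed skeleton.
#' @export
trimEnds <- function(skel) {
  m <- .int_mat(skel)
  repeat {
    nc <- cpp_neighbor_count(m)
    ends <- which(m > 0 & nc == 1, arr.ind = TRUE)
    if (!nrow(ends)) break
    removed <- FALSE
    for (k in seq_len(nrow(ends))) {
      r <- ends[k, 1]; c <- ends[k, 2]
      nb <- .neighbors_on(m, r, c)
      if (nrow(nb) == 1 && nb[1, 1] == r) {
        m[r, c] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

.neighbors_on <- function(m, r, c) {
  rr <- max(1, r - 1):min(nrow(m), r + 1)
  cc <- max(1, c - 1):min(ncol(m), c + 1)
  idx <- which(m[rr, cc, drop = FALSE] > 0, arr.ind = TRUE)
  out <- cbind(rr[idx[, 1]], cc[idx[, 2]])
  out[!(out[, 1] == r & out[, 2] == c), , drop = FALSE]
}

#' Find track seeds
#'
#' Applies a hit-miss transform whose kernel requires the centre pixel
#' on, the three pixels in the previous row and the two lateral pixels in
#' the same row off, and leaves the next row unconstrained - i.e. pixels
#' at which a track starts in time.
#'
#' @param skel trimmed binary skeleton.
#' @return n x 2 matrix of 0-based (row, col) seed coordinates.
#' @export
findSeeds <- function(skel) {
  cpp_hitmiss_seeds(.int_mat(skel))
}

#' Follow one track from a seed
#'
#' Walks forward (same or later rows) from skeleton pixel to skeleton
#' pixel. Whenever the number of continuation candidates differs from
#' one (a branch point, or a dead end left by a thinning artefact) the
#' \code{decide} callback is invoked with the raw kymograph, the full
#' skeleton and the current pixel chain; it returns the chosen future
#' component (n x 2, 0-based) plus a confidence, or NULL to terminate.
#' A returned component is appended only if longer than 2 pixels and its
#' mean trackness is recorded as the decision confidence.
#'
#' @param seed 0-based (row, col) seed.
#' @param skel binary skeleton matrix.
#' @param kymo raw kymograph matrix (context for \code{decide}).
#' @param decide function(kymo, skel, chain) -> list(component,
#'   confidence) or NULL.
#' @param maxSteps iteration cap.
#' @return list with elements chain (n x 2 0-based pixels) and
#'   confidences (numeric, one per accepted decision).
#' @export
followTrack <- function(seed, skel, kymo, decide, maxSteps = 100000L) {
  nr <- nrow(skel); ncl <- ncol(skel)
  inTrack <- matrix(FALSE, nr, ncl)
  chain <- matrix(integer(), 0, 2)
  confs <- numeric()
  cur <- c(seed[1] + 1L, seed[2] + 1L)  # to 1-based
  push <- function(p) {
    chain <<- rbind(chain, p - 1L)
    inTrack[p[1], p[2]] <<- TRUE
  }
  push(cur)
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > maxSteps) break
    nb <- .neighbors_on(skel, cur[1], cur[2])
    if (nrow(nb)) {
      nb <- nb[nb[, 1] >= cur[1] & !inTrack[nb], , drop = FALSE]
    }
    if (nrow(nb) == 1) {
      cur <- c(nb[1, 1], nb[1, 2])
      push(cur)
      next
    }
    # 0 candidates (dead end, e.g. a thinning artefact) or several
    # (branch point): ask the decider for the future path; terminate if
    # it predicts none
    res <- tryCatch(decide(kymo, skel, chain),
                    error = function(e) NULL)
    if (is.null(res) || is.null(res$component) ||
        nrow(res$component) <= 2) break
    comp <- res$component
    comp <- comp[comp[, 1] >= 0 & comp[, 1] < nr &
                   comp[, 2] >= 0 & comp[, 2] < ncl, , drop = FALSE]
    if (nrow(comp) <= 2) break
    comp <- comp[order(comp[, 1], comp[, 2]), , drop = FALSE]
    new <- !inTrack[comp + 1L]
    comp <- comp[new, , drop = FALSE]
    if (nrow(comp) <= 2) break
    for (k in seq_len(nrow(comp))) push(comp[k, ] + 1L)
    confs <- c(confs, res$confidence)
    cur <- comp[nrow(comp), ] + 1L
  }
  list(chain = chain, confidences = confs)
}

#' Decision callback backed by the decision network
#'
#' At a branch point, three 48 x 48 crops are taken with the current
#' track end at the anchor pixel (24, 24) 0-based: the raw kymograph, the
#' full skeleton, and the current-track chain. The network's predicted
#' future-path map is binarized at 0.5 (the precise value has little
#' effect on the output) and thinned; the largest connected component
#' lying at or below the anchor row is returned together with its mean
#' predicted trackness (the decision confidence). An empty prediction
#' signals termination.
#'
#' @param net a trained "decision" \linkS4class{UNetModule}.
#' @param threshold binarization threshold for the predicted map.
#' @return a decide function for \code{\link{followTrack}}.
#' @export
decideNN <- function(net, threshold = 0.5) {
  function(kymo, skel, chain) {
    crop <- 48L; half <- 24L
    end <- chain[nrow(chain), ]
    r0 <- end[1] - half; c0 <- end[2] - half
    inputs <- array(0, c(crop, crop, 3))
    inputs[, , 1] <- .crop_pad(kymo, r0, c0, crop, crop)
    inputs[, , 2] <- 0 + (.crop_pad(skel, r0, c0, crop, crop) > 0)
    segW <- matrix(0, crop, crop)
    inW <- chain[, 1] >= r0 & chain[, 1] < r0 + crop &
           chain[, 2] >= c0 & chain[, 2] < c0 + crop
    if (any(inW))
      segW[cbind(chain[inW, 1] - r0, chain[inW, 2] - c0) + 1L] <- 1
    inputs[, , 3] <- segW
    pred <- predictMap(net, inputs)
    bin <- cpp_thin(.int_mat(matrix(as.integer(pred >= threshold),
                                    crop, crop)))
    # drop the already-traced chain within the crop
    bin[segW > 0] <- 0L
    lab <- cpp_label8(bin)
    if (!any(lab > 0)) return(NULL)
    best <- NULL; bestN <- 0L
    for (l in seq_len(max(lab))) {
      pix <- which(lab == l, arr.ind = TRUE)
      # future path: must reach at/below the anchor row
      if (max(pix[, 1]) < half + 1L) next
      if (nrow(pix) > bestN) { bestN <- nrow(pix); best <- pix }
    }
    if (is.null(best)) return(NULL)
    comp <- cbind(best[, 1] - 1L + r0, best[, 2] - 1L + c0)
    ok <- comp[, 1] >= 0 & comp[, 1] < nrow(skel) &
          comp[, 2] >= 0 & comp[, 2] < ncol(skel) &
          comp[, 1] >= end[1]
    comp <- comp[ok, , drop = FALSE]
    if (!nrow(comp)) return(NULL)
    conf <- mean(pred[best])
    list(component = comp, confidence = conf)
  }
}

#' Ground-truth decision callback
#'
#' For closure tests of the tracing engine: at a branch point, the
#' ground-truth track best matching the current chain is identified and
#' its continuation (the next rows of that track, snapped to the
#' skeleton) is returned with confidence 1.
#'
#' @param gtTracks ground-truth \linkS4class{KymoTracks} or point table.
#' @param lookAhead number of future frames returned per decision.
#' @return a decide function for \code{\link{followTrack}}.
#' @export
decideOracle <- function(gtTracks, lookAhead = 20L) {
  pts <- if (is(gtTracks, "KymoTracks")) as.data.frame(gtTracks) else gtTracks
  per <- split(pts, pts$id)
  function(kymo, skel, chain) {
    # identify the track from the recent chain tail (the whole chain can
    # span several crossings; the tail is what the walk is currently on)
    tl <- chain[max(1, nrow(chain) - 19):nrow(chain), , drop = FALSE]
    overlap <- vapply(per, function(tr)
      sum(vapply(seq_len(nrow(tr)), function(k)
        any(tl[, 1] == tr$frame[k] &
              abs(tl[, 2] - tr$position[k]) <= 1.5), logical(1))),
      numeric(1))
    if (max(overlap) == 0) return(NULL)
    tr <- per[[which.max(overlap)]]
    endRow <- chain[nrow(chain), 1]
    fut <- tr[tr$frame > endRow & tr$frame <= endRow + lookAhead, ,
              drop = FALSE]
    if (nrow(fut) < 3) return(NULL)
    comp <- cbind(fut$frame, round(fut$position))
    comp <- .snap_to_skeleton(comp, skel)
    if (nrow(comp) < 3) return(NULL)
    list(component = comp, confidence = 1)
  }
}

.snap_to_skeleton <- function(comp, skel) {
  out <- matrix(integer(), 0, 2)
  for (k in seq_len(nrow(comp))) {
    r <- comp[k, 1]; c <- comp[k, 2]
    if (r < 0 || r >= nrow(skel)) next
    found <- FALSE
    for (dc in c(0, -1, 1, -2, 2)) {
      c2 <- c + dc
      if (c2 >= 0 && c2 < ncol(skel) && skel[r + 1, c2 + 1] > 0) {
        out <- rbind(out, c(r, c2)); found <- TRUE; break
      }
    }
    if (!found) out <- rbind(out, c(r, max(0, min(c, ncol(skel) - 1))))
  }
  out[!duplicated(out), , drop = FALSE]
}

#' Consolidate raw pixel chains into tracks
#'
#' Pixels in the same kymograph row are averaged so each track has one
#' position per frame; tracks that are part of another track (at least
#' \code{containFrac} of their pixels contained in a longer track — the
#' re-seeding rounds retrace already-found paths with pixel-level
#' snapping differences, so literal subsets are too strict) are removed;
#' tracks shorter than \code{minPx} skeleton pixels are removed;
#' overlapping runs longer than \code{overlapLen} pixels are assigned
#' uniquely to the track with the highest mean decision confidence
#' (ties, and tracks without confidences, resolved by seeded random
#' draw).
#'
#' @param rawTracks list of \code{\link{followTrack}} results.
#' @param minPx minimum chain length in skeleton pixels.
#' @param overlapLen overlap run length above which unique assignment is
#'   enforced.
#' @param containFrac containment fraction above which a track counts as
#'   part of another (1 = strict subset only).
#' @param seed seed for random tie-breaks.
#' @return a \linkS4class{KymoTracks}.
#' @export
consolidateTracks <- function(rawTracks, minPx = 5L, overlapLen = 10L,
                              containFrac = 0.9, seed = 1L) {
  rawTracks <- Filter(function(rt) nrow(rt$chain) >= minPx, rawTracks)
  if (!length(rawTracks)) return(kymoTracks())
  keys <- lapply(rawTracks, function(rt)
    unique(rt$chain[, 1] * 1e6 + rt$chain[, 2]))
  n <- length(rawTracks)
  subset <- logical(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || subset[b]) next
      if (length(keys[[a]]) <= length(keys[[b]]) &&
          mean(keys[[a]] %in% keys[[b]]) >= containFrac &&
          !(length(keys[[a]]) == length(keys[[b]]) && a < b)) {
        subset[a] <- TRUE
        break
      }
    }
  }
  rawTracks <- rawTracks[!subset]
  if (!length(rawTracks)) return(kymoTracks())
  conf <- vapply(rawTracks, function(rt)
    if (length(rt$confidences)) mean(rt$confidences) else 1, numeric(1))
  # decision-free tracks default to confidence 1; NA (e.g. the wavelet
  # baseline's linear prediction) triggers random overlap assignment
  tie <- .with_seed(seed, runif(length(rawTracks)))
  # per-row averaged points, as data.frames
  tracks <- lapply(rawTracks, function(rt) {
    ch <- rt$chain
    pos <- tapply(ch[, 2], ch[, 1], mean)
    data.frame(frame = as.integer(names(pos)), position = as.numeric(pos))
  })
  # unique assignment of long shared runs
  npx <- vapply(rawTracks, function(rt) nrow(rt$chain), integer(1))
  for (a in seq_along(tracks)) {
    for (b in seq_along(tracks)) {
      if (a >= b) next
      ta <- tracks[[a]]; tb <- tracks[[b]]
      if (!nrow(ta) || !nrow(tb)) next
      if (min(ta$frame) > max(tb$frame) || min(tb$frame) > max(ta$frame))
        next
      common <- intersect(ta$frame, tb$frame)
      if (!length(common)) next
      shared <- common[abs(ta$position[match(common, ta$frame)] -
                           tb$position[match(common, tb$frame)]) < 1]
      if (!length(shared)) next
      shared <- sort(shared)
      runs <- split(shared, cumsum(c(1, diff(shared) != 1)))
      for (run in runs) {
        if (length(run) <= overlapLen) next
        ca <- conf[a]; cb <- conf[b]
        loser <- if (!is.na(ca) && !is.na(cb) && ca != cb) {
          if (ca > cb) b else a
        } else if (!is.na(ca) && !is.na(cb) && npx[a] != npx[b]) {
          # equal confidence: keep the run on the longer track; pure
          # random assignment is reserved for confidence-free tracing
          # (the wavelet baseline)
          if (npx[a] > npx[b]) b else a
        } else if (tie[a] > tie[b]) b else a
        tracks[[loser]] <-
          tracks[[loser]][!(tracks[[loser]]$frame %in% run), , drop = FALSE]
      }
    }
  }
  keep <- vapply(seq_along(tracks), function(i)
    nrow(tracks[[i]]) >= 2 && npx[i] >= minPx, logical(1))
  tracks <- tracks[keep]; conf <- conf[keep]
  if (!length(tracks)) return(kymoTracks())
  pts <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(id = i, tracks[[i]])))
  kymoTracks(pts, info = data.frame(id = seq_along(tracks),
                                    meanConfidence = conf))
}

#' Extract tracks from unidirectional trackness maps
#'
#' Each slope map is independently binarized, thinned and pruned;
#' 8-connected components become candidate tracks, filtered to span at
#' least \code{minFrames} frames and contain at least \code{minPx}
#' skeleton pixels; same-row pixels are averaged to one position per
#' frame.
#'
#' @param posMap,negMap trackness maps for positive- and negative-slope
#'   tracks (matrices in [0, 1]).
#' @param threshold binarization threshold.
#' @param minFrames,minPx track selection filters.
#' @return a \linkS4class{KymoTracks}.
#' @export
extractUnidirectionalTracks <- function(posMap, negMap, threshold = 0.2,
                                        minFrames = 3L, minPx = 3L) {
  pts <- list(); nextId <- 0L
  for (map in list(posMap, negMap)) {
    skel <- thinPrune(binarizeMap(map, threshold))
    lab <- cpp_label8(skel)
    nlab <- max(lab)
    if (nlab == 0) next
    for (l in seq_len(nlab)) {
      pix <- which(lab == l, arr.ind = TRUE)
      if (nrow(pix) < minPx) next
      if (diff(range(pix[, 1])) + 1L < minFrames) next
      pos <- tapply(pix[, 2] - 1, pix[, 1] - 1, mean)
      nextId <- nextId + 1L
      pts[[length(pts) + 1]] <- data.frame(
        id = nextId, frame = as.integer(names(pos)),
        position = as.numeric(pos))
    }
  }
  if (!length(pts)) return(kymoTracks())
  kymoTracks(do.call(rbind, pts))
}

#' Trace a skeleton with a pluggable branch-point decider
#'
#' The shared tracing engine: trims ends, finds seeds, follows every
#' seed, then subtracts the found paths from the skeleton and re-seeds
#' until no seeds remain (bounded by \code{maxRounds}), and finally
#' consolidates. Both the network pipeline and the wavelet baseline run
#' through this entry point, differing only in the \code{decide}
#' callback.
#'
#' @param kymo raw kymograph (matrix or \linkS4class{Kymograph}).
#' @param skel binary skeleton matrix.
#' @param decide branch decision callback.
#' @param minPx,overlapLen consolidation parameters.
#' @param maxRounds cap on re-seeding rounds.
#' @param seed seed for consolidation tie-breaks.
#' @return a \linkS4class{KymoTracks}.
#' @export
traceSkeleton <- function(kymo, skel, decide, minPx = 5L, overlapLen = 10L,
                          maxRounds = 20L, seed = 1L) {
  kymo <- normalizeImage(kymoPixels(kymo))  # deciders receive the
  skel <- trimEnds(skel)                    # contrast-normalised image
  work <- skel
  raw <- list()
  for (round in seq_len(maxRounds)) {
    seeds <- findSeeds(work)
    if (!nrow(seeds)) break
    found <- matrix(0L, nrow(skel), ncol(skel))
    for (k in seq_len(nrow(seeds))) {
      rt <- followTrack(seeds[k, ], skel, kymo, decide)
      raw[[length(raw) + 1]] <- rt
      found[rt$chain + 1L] <- 1L
    }
    work2 <- work
    work2[found > 0] <- 0L
    if (identical(work2, work)) break
    work <- work2
  }
  consolidateTracks(raw, minPx = minPx, overlapLen = overlapLen, seed = seed)
}

#' Run the full tracing pipeline on a kymograph
#'
#' The classification module routes the kymograph to the unidirectional
#' path (two slope-specific trackness maps, component extraction) or the
#' bidirectional path (one trackness map, skeleton tracing with the
#' decision module); \code{mode} can force either route.
#'
#' @param kymo matrix or \linkS4class{Kymograph}.
#' @param models list with elements class, uniseg, biseg, decision
#'   (\linkS4class{UNetModule}s; only those needed for the chosen route
#'   are required).
#' @param threshold trackness binarization threshold (the pipeline's one
#'   free parameter; default 0.2).
#' @param mode "auto", "uni" or "bi".
#' @param minFrames,minPx unidirectional track filters.
#' @param seed seed for consolidation tie-breaks.
#' @return a \linkS4class{KymoTracks} with attribute "mode" set to the
#'   route taken.
#' @export
runPipeline <- function(kymo, models, threshold = 0.2,
                        mode = c("auto", "uni", "bi"), minFrames = 3L,
                        minPx = 3L, seed = 1L) {
  mode <- match.arg(mode)
  px <- kymoPixels(kymo)
  if (mode == "auto") {
    if (is.null(models$class)) stop("mode 'auto' needs a class module")
    p <- predictMap(models$class, px)
    mode <- if (p["uni"] >= p["bi"]) "uni" else "bi"
  }
  if (mode == "uni") {
    if (is.null(models$uniseg)) stop("unidirectional route needs 'uniseg'")
    maps <- predictMap(models$uniseg, px)
    out <- extractUnidirectionalTracks(maps[, , 1], maps[, , 2], threshold,
                                       minFrames = minFrames, minPx = minPx)
  } else {
    if (is.null(models$biseg) || is.null(models$decision))
      stop("bidirectional route needs 'biseg' and 'decision'")
    map <- predictMap(models$biseg, px)
    skel <- thinPrune(binarizeMap(map, threshold))
    out <- traceSkeleton(px, skel, decideNN(models$decision), seed = seed)
  }
  attr(out, "mode") <- mode
  out
}
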