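# Image and track I/O plus kymograph extraction from time-lapse movies
# along a user-supplied path.

#' Path specification for kymograph extraction
#'
#' @param polyline n x 2 matrix of (row, col) control points in
#'   movie-frame coordinates (0-based, fractional allowed).
#' @param width transverse averaging width in pixels (odd values centre
#'   the path).
#' @return a list of class spec used by \code{\link{extractKymograph}}.
#' @export
pathSpec <- function(polyline, width = 1L) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2, nrow(polyline) >= 2, width >= 1)
  list(polyline = polyline, width = as.integer(width))
}

.bilinear <- function(img, r, c) {
  # r, c are 0-based fractional coordinates; out-of-bounds clamps
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 0), nr - 1); c <- pmin(pmax(c, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    img[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
    img[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
    img[cbind(r1 + 1, c1 + 1)] * fr * fc
}

#' Extract a kymograph from a movie along a path
#'
#' For every movie frame, intensities are sampled at unit arc-length
#' steps along the polyline by bilinear interpolation; across the
#' transverse width the samples are aggregated by max (default, robust to
#' small transverse jitter) or mean. Output rows are ordered by frame.
#'
#' @param movie array (transverse rows x longitudinal columns x frames),
#'   as stored in \linkS4class{SyntheticSample} movies.
#' @param path a \code{\link{pathSpec}}.
#' @param aggregator "max" or "mean".
#' @return a \linkS4class{Kymograph} with one row per frame.
#' @export
extractKymograph <- function(movie, path, aggregator = c("max", "mean")) {
  aggregator <- match.arg(aggregator)
  stopifnot(length(dim(movie)) == 3)
  pl <- path$polyline
  if (any(pl[, 1] < 0) || any(pl[, 1] > dim(movie)[1] - 1) ||
      any(pl[, 2] < 0) || any(pl[, 2] > dim(movie)[2] - 1))
    stop("path outside movie bounds")
  # resample polyline at unit arc length
  seg <- sqrt(rowSums(diff(pl)^2))
  cum <- c(0, cumsum(seg))
  svals <- seq(0, cum[length(cum)])
  pr <- approx(cum, pl[, 1], xout = svals)$y
  pc <- approx(cum, pl[, 2], xout = svals)$y
  # unit normals from local tangent
  tr <- c(diff(pr), tail(diff(pr), 1)); tc <- c(diff(pc), tail(diff(pc), 1))
  nrm <- sqrt(tr^2 + tc^2); nrm[nrm == 0] <- 1
  nr <- -tc / nrm; nc <- tr / nrm
  offs <- seq_len(path$width) - (path$width + 1) / 2
  nF <- dim(movie)[3]
  out <- matrix(0, nF, length(svals))
  for (f in seq_len(nF)) {
    frame <- movie[, , f]
    samp <- vapply(offs, function(o)
      .bilinear(frame, pr + o * nr, pc + o * nc), numeric(length(svals)))
    samp <- matrix(samp, nrow = length(svals))
    out[f, ] <- if (aggregator == "max") apply(samp, 1, max)
                else rowMeans(samp)
  }
  Kymograph(out)
}

#' Read / write multi-page TIFF movies and kymographs
#'
#' Movies are stored with one page per frame (transverse x longitudinal).
#'
#' @param movie array (transverse x longitudinal x frames).
#' @param path file path.
#' @param bitsPerSample 32 (float) or 16 (integer, intensities rescaled
#'   to the sample maximum).
#' @return \code{readMovieTiff} returns the array; writers return the
#'   path invisibly.
#' @export
writeMovieTiff <- function(movie, path, bitsPerSample = 32L) {
  mx <- max(movie, 1e-12)  # TIFF intensities are stored scaled to [0, 1]
  frames <- lapply(seq_len(dim(movie)[3]), function(f) movie[, , f] / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = bitsPerSample)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' @rdname writeMovieTiff
#' @param kymo a \linkS4class{Kymograph} or matrix.
#' @export
writeKymographTiff <- function(kymo, path) {
  px <- kymoPixels(kymo)
  tiff::writeTIFF(px / max(px, 1e-12), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readKymographTiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  Kymograph(px)
}

#' Write tracing outputs
#'
#' Writes (a) a track-coordinates CSV (track_id, frame, position;
#' fractional positions preserved), (b) a kinematic summary CSV (one row
#' per track plus one aggregate row, see
#' \code{\link{summarizeKymograph}}), and (c) a colour overlay PNG in
#' which each track is drawn in a distinct colour and dilated once with a
#' 3x3 box for visibility. File contents are deterministic given
#' \code{colorSeed}.
#'
#' @param tracks a \linkS4class{KymoTracks}.
#' @param kymo the traced \linkS4class{Kymograph} (used as overlay
#'   background and for raster dimensions).
#' @param outDir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param mode "uni" or "bi"; forwarded to the kinematic summary.
#' @param colorSeed seed for the random track colours.
#' @return invisibly, the named vector of file paths.
#' @export
writeOutputs <- function(tracks, kymo, outDir, prefix = "kymo",
                         mode = "bi", colorSeed = 1L) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  px <- kymoPixels(kymo)
  pts <- as.data.frame(tracks)
  coordsFile <- file.path(outDir, paste0(prefix, "_tracks.csv"))
  write.csv(data.frame(track_id = pts$id, frame = pts$frame,
                       position = pts$position),
            coordsFile, row.names = FALSE)
  summaryFile <- file.path(outDir, paste0(prefix, "_summary.csv"))
  write.csv(summarizeKymograph(tracks, mode = mode, perTrack = TRUE),
            summaryFile, row.names = FALSE)
  overlayFile <- file.path(outDir, paste0(prefix, "_overlay.png"))
  ov <- trackOverlay(tracks, dim(px), background = px, colorSeed = colorSeed)
  png::writePNG(ov, overlayFile)
  plotsFile <- file.path(outDir, paste0(prefix, "_plots.png"))
  plotTrackSummary(tracks, plotsFile, mode = mode)
  invisible(c(tracks = coordsFile, summary = summaryFile,
              overlay = overlayFile, plots = plotsFile))
}

#' Render a colour overlay of tracks
#'
#' @param tracks a \linkS4class{KymoTracks}.
#' @param dims c(nFrames, pathLength) raster size.
#' @param background optional grayscale matrix drawn underneath.
#' @param colorSeed seed for the per-track hues.
#' @return an nFrames x pathLength x 3 RGB array in [0, 1].
#' @export
trackOverlay <- function(tracks, dims, background = NULL, colorSeed = 1L) {
  ov <- array(0, dim = c(dims, 3))
  if (!is.null(background)) {
    bg <- background / max(background, 1e-12)
    for (ch in 1:3) ov[, , ch] <- 0.5 * bg
  }
  ids <- trackIds(tracks)
  hues <- .with_seed(colorSeed, runif(max(length(ids), 1)))
  brush <- matrix(1, 3, 3)
  pts <- as.data.frame(tracks)
  for (k in seq_along(ids)) {
    tr <- pts[pts$id == ids[k], ]
    m <- matrix(0L, dims[1], dims[2])
    r <- tr$frame + 1L
    c <- pmin(pmax(round(tr$position), 0), dims[2] - 1) + 1L
    ok <- r >= 1 & r <= dims[1]
    m[cbind(r[ok], c[ok])] <- 1L
    m <- EBImage::dilate(m, brush)
    col <- hsv(hues[k], 0.9, 1)
    rgb <- grDevices::col2rgb(col) / 255
    for (ch in 1:3) {
      plane <- ov[, , ch]
      plane[m > 0] <- rgb[ch]
      ov[, , ch] <- plane
    }
  }
  ov
}

#' Preliminary summary plots
#'
#' Writes a two-panel PNG: a histogram of per-track mean speeds and a
#' bar chart of track directionality counts.
#'
#' @param tracks a \linkS4class{KymoTracks} or point table.
#' @param path output PNG path.
#' @param mode "uni" or "bi".
#' @return the path, invisibly.
#' @export
plotTrackSummary <- function(tracks, path, mode = "bi") {
  sm <- summarizeKymograph(tracks, mode = mode, perTrack = TRUE)
  per <- sm[!is.na(sm$id), , drop = FALSE]
  grDevices::png(path, width = 800, height = 400)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  if (nrow(per)) {
    graphics::hist(per$meanSpeed, main = "Mean speed per track",
                   xlab = "px/frame", col = "grey70", border = "white")
    counts <- table(factor(per$directionality, levels = c(-1, 0, 1)))
    graphics::barplot(counts, main = "Directionality",
                      names.arg = c("-1", "0", "+1"), col = "grey70")
  } else {
    graphics::plot.new(); graphics::title("no tracks")
    graphics::plot.new()
  }
  invisible(path)
}

#' Read a track-coordinates CSV written by \code{\link{writeOutputs}}
#'
#' @param path CSV path.
#' @return a \linkS4class{KymoTracks}.
#' @export
readTracksCSV <- function(path) {
  df <- read.csv(path)
  kymoTracks(data.frame(id = df$track_id, frame = df$frame,
                        position = df$position))
}
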