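#' Kymograph image
#'
#' A 2D intensity image in which rows are movie frames (time) and columns
#' are positions along the stationary path.
#'
#' @slot pixels numeric matrix of intensities (rows = frames).
#' @slot frameInterval seconds per frame (NA if unknown).
#' @slot pixelSize micrometres per pixel (NA if unknown).
#' @export
setClass("Kymograph",
  representation(pixels = "matrix", frameInterval = "numeric",
                 pixelSize = "numeric"),
  prototype(frameInterval = NA_real_, pixelSize = NA_real_),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(!is.finite(object@pixels))) return("pixels must be finite")
    TRUE
  })

#' Construct a Kymograph
#'
#' @param pixels numeric matrix, rows = frames, columns = path position.
#' @param frameInterval optional seconds per frame.
#' @param pixelSize optional micrometres per pixel.
#' @return A \linkS4class{Kymograph}.
#' @examples
#' k <- Kymograph(matrix(runif(100), 10, 10))
#' dim(kymoPixels(k))
#' @export
Kymograph <- function(pixels, frameInterval = NA_real_, pixelSize = NA_real_) {
  new("Kymograph", pixels = unname(as.matrix(pixels)),
      frameInterval = frameInterval, pixelSize = pixelSize)
}

#' @describeIn Kymograph the pixel matrix.
#' @param x,object a Kymograph.
#' @export
kymoPixels <- function(x) {
  if (is(x, "Kymograph")) x@pixels else as.matrix(x)
}

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Kymograph: %d frames x %d px, intensity range [%.3g, %.3g]\n",
              d[1], d[2], min(object@pixels), max(object@pixels)))
})

#' Assembled particle tracks
#'
#' A set of traced tracks with at most one (possibly fractional) position
#' per frame per track. Frames and positions are 0-based.
#'
#' @slot points data.frame with columns id, frame, position.
#' @slot info data.frame with columns id, meanConfidence.
#' @export
setClass("KymoTracks",
  representation(points = "data.frame", info = "data.frame"),
  validity = function(object) {
    p <- object@points
    if (!all(c("id", "frame", "position") %in% names(p)))
      return("points needs columns id, frame, position")
    if (nrow(p)) {
      dup <- any(vapply(split(p$frame, p$id),
                        function(f) anyDuplicated(f) > 0, logical(1)))
      if (dup) return("at most one position per frame per track")
    }
    TRUE
  })

#' Construct a KymoTracks object
#'
#' @param points data.frame with columns id, frame (0-based, strictly
#'   increasing within a track), position (0-based, fractional allowed).
#' @param info optional data.frame with columns id, meanConfidence; tracks
#'   traced without any contested branch point get confidence 1.
#' @return A \linkS4class{KymoTracks}.
#' @export
kymoTracks <- function(points = data.frame(id = integer(), frame = integer(),
                                           position = numeric()),
                       info = NULL) {
  points <- as.data.frame(points)[, c("id", "frame", "position")]
  points <- points[order(points$id, points$frame), , drop = FALSE]
  rownames(points) <- NULL
  if (is.null(info)) {
    ids <- unique(points$id)
    info <- data.frame(id = ids, meanConfidence = rep(1, length(ids)))
  }
  new("KymoTracks", points = points, info = as.data.frame(info))
}

#' @describeIn kymoTracks number of tracks.
#' @param x a KymoTracks object.
#' @export
nTracks <- function(x) length(unique(x@points$id))

#' @describeIn kymoTracks the track ids.
#' @export
trackIds <- function(x) unique(x@points$id)

#' @describeIn kymoTracks split the point table into one data.frame per track.
#' @export
trackList <- function(x) split(x@points[, c("frame", "position")], x@points$id)

setMethod("show", "KymoTracks", function(object) {
  cat(sprintf("KymoTracks: %d tracks, %d points\n",
              nTracks(object), nrow(object@points)))
})

#' @export
setMethod("as.data.frame", "KymoTracks",
          function(x, ...) x@points)

#' Synthetic kymograph sample
#'
#' One simulated movie/kymograph together with its ground-truth tracks,
#' the rendering configuration and the realised signal-to-noise ratio.
#'
#' @slot kymograph the rendered \linkS4class{Kymograph}.
#' @slot movie transverse x longitudinal x frame array, or NULL.
#' @slot tracks ground-truth table: id, frame, position, visible,
#'   amplitude, psf (+ moving for bidirectional simulations).
#' @slot config the simulator configuration list.
#' @slot seed integer seed the sample was generated from.
#' @slot measuredSNR realised signal/background intensity ratio.
#' @slot noiseSigma calibrated Gaussian noise sigma.
#' @slot signalMask logical matrix marking signal pixels.
#' @export
setClass("SyntheticSample",
  representation(kymograph = "Kymograph", movie = "ANY", tracks = "data.frame",
                 config = "list", seed = "integer", measuredSNR = "numeric",
                 noiseSigma = "numeric", signalMask = "matrix"))

setMethod("show", "SyntheticSample", function(object) {
  cat(sprintf(
    "SyntheticSample (%s): %d frames x %d px, %d tracks, SNR %.3g (seed %d)\n",
    object@config$mode, nrow(object@kymograph@pixels),
    ncol(object@kymograph@pixels), length(unique(object@tracks$id)),
    object@measuredSNR, object@seed))
})

#' @describeIn SyntheticSample-class the rendered kymograph.
#' @param x,object a SyntheticSample.
#' @export
kymograph <- function(x) x@kymograph

#' @describeIn SyntheticSample-class ground-truth tracks as KymoTracks
#'   (all points, including those hidden inside artificial gaps).
#' @export
groundTruth <- function(x) kymoTracks(x@tracks[, c("id", "frame", "position")])

#' @describeIn SyntheticSample-class realised signal-to-noise ratio.
#' @export
measuredSNR <- function(x) x@measuredSNR

#' @describeIn SyntheticSample-class table of artificial signal gaps:
#'   one row per gap with columns id, start (first invisible frame),
#'   len (gap length in frames).
#' @export
gapTable <- function(x) {
  gt <- x@tracks
  out <- do.call(rbind, lapply(split(gt, gt$id), function(tr) {
    r <- rle(!tr$visible)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- which(r$values)
    data.frame(id = tr$id[1], start = tr$frame[starts[k]], len = r$lengths[k])
  }))
  if (is.null(out))
    out <- data.frame(id = integer(), start = integer(), len = integer())
  rownames(out) <- NULL
  out
}

#' Trained network module handle
#'
#' Wraps the compiled U-Net (classification, unidirectional segmentation,
#' bidirectional segmentation, or branch-point decision variant).
#'
#' @slot ptr external pointer to the compiled network.
#' @slot kind one of "class", "uniseg", "biseg", "decision".
#' @slot config list with base width, depth, channel counts, seed.
#' @export
setClass("UNetModule",
  representation(ptr = "externalptr", kind = "character", config = "list"))

setMethod("show", "UNetModule", function(object) {
  cat(sprintf("UNetModule '%s': base width %d, depth %d, %s parameters\n",
              object@kind, object@config$base, object@config$depth,
              format(cpp_unet_nparams(object@ptr), big.mark = ",")))
})

#' Benchmark report
#'
#' Per-kymograph track recall/precision/F1, gap-bridging and
#' crossing-resolution fractions, plus set-level medians.
#'
#' @slot perKymograph data.frame, one row per kymograph.
#' @slot medians named numeric vector of set medians.
#' @export
setClass("BenchmarkReport",
  representation(perKymograph = "data.frame", medians = "numeric"))

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport: %d kymographs\n", nrow(object@perKymograph)))
  m <- object@medians
  cat(sprintf("  median F1 %.3f | gaps %.3f | crossings %.3f\n",
              m["f1"], m["gapScore"], m["crossingScore"]))
})

#' @describeIn BenchmarkReport-class per-kymograph score table.
#' @param x,object a BenchmarkReport.
#' @export
perKymograph <- function(x) x@perKymograph

#' @describeIn BenchmarkReport-class named vector of set medians.
#' @export
reportMedians <- function(x) x@medians
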