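# Classical comparator: stationary-wavelet-transform trackness with a
# fixed binarization threshold and linear-prediction branch resolution.
# Kept as a benchmark baseline, not a recommended tracer: it was tuned on
# the synthetic kymographs and does not generalise the way the trained
# modules do.

#' Wavelet baseline parameters
#'
#' @param levels number of stationary-wavelet decomposition levels.
#' @param bands which Haar detail bands to overlay: subsets of "LH"
#'   (detail along time, smooth along position: emphasises horizontal
#'   structure), "HL" (detail along position: vertical structure), "HH".
#' @param threshold binarization threshold on the rescaled overlay.
#' @return a parameter list.
#' @export
waveletParams <- function(levels = 2L, bands = c("LH", "HL"),
                          threshold = 0.3) {
  stopifnot(levels >= 1, threshold > 0, threshold < 1,
            all(bands %in% c("LH", "HL", "HH")))
  list(levels = as.integer(levels), bands = bands, threshold = threshold)
}

# Undecimated (a trous) 2D Haar transform. At level j the low/high pair
# acts on pixels 2^(j-1) apart; replicate padding at the borders. Returns
# per level the LH, HL and HH detail images (same size as the input).
#' Stationary 2D Haar wavelet transform
#'
#' @param img numeric matrix.
#' @param levels decomposition depth.
#' @return list with one element per level, each a list of same-size
#'   coefficient images LL, LH, HL, HH.
#' @export
swtHaar2 <- function(img, levels = 2L) {
  shift_rows <- function(m, d) m[pmin(pmax(seq_len(nrow(m)) + d, 1), nrow(m)), ,
                                 drop = FALSE]
  shift_cols <- function(m, d) m[, pmin(pmax(seq_len(ncol(m)) + d, 1), ncol(m)),
                                 drop = FALSE]
  out <- vector("list", levels)
  a <- img
  for (j in seq_len(levels)) {
    d <- 2^(j - 1)
    lr <- (a + shift_rows(a, d)) / 2      # low along time (rows)
    hr <- (a - shift_rows(a, d)) / 2      # high along time
    LL <- (lr + shift_cols(lr, d)) / 2
    LH <- (hr + shift_cols(hr, d)) / 2    # high time, low position
    HL <- (lr - shift_cols(lr, d)) / 2    # low time, high position
    HH <- (hr - shift_cols(hr, d)) / 2
    out[[j]] <- list(LL = LL, LH = LH, HL = HL, HH = HH)
    a <- LL
  }
  out
}

#' Wavelet trackness skeleton
#'
#' Computes the stationary Haar transform, rescales the absolute values
#' of the selected detail-coefficient images to [0, 1], overlays them by
#' pixelwise maximum, binarizes at the fixed threshold and thins
#' iteratively.
#'
#' @param kymo matrix or \linkS4class{Kymograph} (normalised internally).
#' @param params a \code{\link{waveletParams}} list.
#' @return binary skeleton matrix.
#' @export
waveletSkeleton <- function(kymo, params = waveletParams()) {
  img <- normalizeImage(kymoPixels(kymo))
  sw <- swtHaar2(img, params$levels)
  overlay <- matrix(0, nrow(img), ncol(img))
  for (j in seq_len(params$levels))
    for (b in params$bands) {
      m <- abs(sw[[j]][[b]])
      rg <- range(m)
      if (diff(rg) > 1e-12) m <- (m - rg[1]) / diff(rg)
      overlay <- pmax(overlay, m)
    }
  thinPrune(binarizeMap(overlay, params$threshold))
}

#' Linear-prediction branch resolution
#'
#' The classical stand-in for the decision network: the terminal segment
#' of the current track is dilated once (3 x 3), rotated by 180 degrees
#' about the track end, multiplied with the skeleton map, and the largest
#' connected component of the product returned. No confidence is
#' produced (NA), so downstream overlap assignment is random.
#'
#' @param segLen how many terminal chain pixels form the segment.
#' @return a decide function for \code{\link{followTrack}}.
#' @export
linearPredict <- function(segLen = 10L) {
  function(kymo, skel, chain) {
    n <- nrow(chain)
    if (n < 2) return(NULL)
    seg <- chain[max(1, n - segLen + 1):n, , drop = FALSE]
    end <- chain[n, ]
    # work in a window around the track end: the rotated segment can
    # reach at most segLen + 1 px (+1 for the dilation)
    half <- segLen + 2L
    r0 <- end[1] - half; c0 <- end[2] - half
    win <- 2L * half + 1L
    skW <- .crop_pad(skel, r0, c0, win, win)
    segW <- matrix(0L, win, win)
    sr <- seg[, 1] - r0; sc <- seg[, 2] - c0
    ok <- sr >= 0 & sr < win & sc >= 0 & sc < win
    segW[cbind(sr[ok], sc[ok]) + 1L] <- 1L
    segW <- .int_mat(EBImage::dilate(segW, matrix(1, 3, 3)))
    # rotate 180 degrees about the end pixel (window centre):
    # p -> 2*centre - p, i.e. reverse both axes
    pred <- segW[win:1, win:1]
    prod <- pred * (0 + (skW > 0))
    # exclude what is already traced
    chW <- chain[, 1] >= r0 & chain[, 1] < r0 + win &
           chain[, 2] >= c0 & chain[, 2] < c0 + win
    if (any(chW))
      prod[cbind(chain[chW, 1] - r0, chain[chW, 2] - c0) + 1L] <- 0L
    lab <- cpp_label8(.int_mat(prod))
    if (!any(lab > 0)) return(NULL)
    sizes <- tabulate(lab[lab > 0])
    best <- which.max(sizes)
    comp <- which(lab == best, arr.ind = TRUE) - 1L
    comp <- cbind(comp[, 1] + r0, comp[, 2] + c0)
    comp <- comp[comp[, 1] >= end[1] & comp[, 1] >= 0 & comp[, 2] >= 0 &
                   comp[, 1] < nrow(skel) & comp[, 2] < ncol(skel), ,
                 drop = FALSE]
    if (!nrow(comp)) return(NULL)
    list(component = comp, confidence = NA_real_)
  }
}

#' Trace a kymograph with the wavelet baseline
#'
#' Wavelet skeleton, then the shared tracing engine
#' (\code{\link{traceSkeleton}}) with \code{\link{linearPredict}} as the
#' branch decider and seeded random overlap assignment.
#'
#' @param kymo matrix or \linkS4class{Kymograph}.
#' @param params \code{\link{waveletParams}}.
#' @param seed seed for the random overlap assignment.
#' @return a \linkS4class{KymoTracks}.
#' @export
traceWavelet <- function(kymo, params = waveletParams(), seed = 1L) {
  skel <- waveletSkeleton(kymo, params)
  traceSkeleton(kymoPixels(kymo), skel, linearPredict(), seed = seed)
}
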