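# Synthetic particle simulators. Both simulators place particles on a
# stationary path of length pathLength for nFrames frames and render a
# kymograph (and optionally a short transverse movie) with a Gaussian
# point-spread profile on a constant baseline of 1, plus additive Gaussian
# noise whose sigma is calibrated so the realised signal-to-noise ratio
# (mean signal intensity / mean background intensity) hits the target.

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Unidirectional simulator configuration
#'
#' Defaults reproduce the benchmark conditions: a 300 px path observed for
#' 300 frames, 30 + 30 particles with positive or negative slope seeded at
#' random times/positions, one movie-wide base speed drawn from 1-3
#' px/frame with small per-frame jitter, Gaussian point-spread widths
#' (FWHM) of 3-6 px, exponential lifetimes with rate 0.01 per frame,
#' exponentially distributed interior signal gaps clipped at 6 frames, and
#' noise calibrated to a signal-to-noise ratio of 1.2.
#'
#' @param pathLength path length in pixels.
#' @param nFrames number of movie frames.
#' @param nPerDirection particles per slope sign.
#' @param speedRange interval the movie-wide base speed is drawn from
#'   (px/frame).
#' @param speedNoise half-width of the uniform per-frame velocity jitter
#'   (px/frame).
#' @param psfRange interval particle PSF full widths at half maximum are
#'   drawn from (px).
#' @param survivalRate exponential lifetime rate per frame (mean lifetime
#'   1/survivalRate frames).
#' @param gapRate expected number of gaps per track point.
#' @param gapMeanLen mean of the exponential gap-length draw (frames).
#' @param maxGapLen hard clip on gap length (frames).
#' @param targetSNR target mean signal / mean background intensity ratio.
#' @param movieWidth transverse movie extent in pixels.
#' @param amplitude peak signal amplitude above the unit baseline.
#' @return a configuration list.
#' @examples
#' cfg <- uniSimConfig(nPerDirection = 5)
#' @export
uniSimConfig <- function(pathLength = 300L, nFrames = 300L,
                         nPerDirection = 30L, speedRange = c(1, 3),
                         speedNoise = 0.1, psfRange = c(3, 6),
                         survivalRate = 0.01, gapRate = 0.035,
                         gapMeanLen = 2, maxGapLen = 6L, targetSNR = 1.2,
                         movieWidth = 20L, amplitude = 0.3) {
  stopifnot(pathLength >= 1, nFrames >= 1, nPerDirection >= 0,
            all(speedRange > 0), diff(speedRange) >= 0, survivalRate > 0,
            maxGapLen >= 1, speedNoise >= 0)
  list(mode = "uni", pathLength = as.integer(pathLength),
       nFrames = as.integer(nFrames),
       nPerDirection = as.integer(nPerDirection), speedRange = speedRange,
       speedNoise = speedNoise, psfRange = psfRange,
       survivalRate = survivalRate, gapRate = gapRate,
       gapMeanLen = gapMeanLen, maxGapLen = as.integer(maxGapLen),
       targetSNR = targetSNR, movieWidth = as.integer(movieWidth),
       amplitude = amplitude)
}

#' Bidirectional simulator configuration
#'
#' Defaults reproduce the complex-motion benchmark: 15 particles (use
#' \code{nTracks = 30} for training sets) on a 300 x 300 kymograph,
#' maximum speed 3 px/frame, with a per-movie velocity-noise half-width
#' drawn from [0, 1.5] px/frame, a per-movie probability of switching
#' between stationary and directed movement drawn from [0, 0.1] per frame,
#' a per-movie velocity-flip probability drawn from [0, 0.1] per frame,
#' exponential lifetimes with rate 0.001 per frame, particle sizes (PSF
#' FWHM) of 1-6 px, particle amplitudes of 0.35-1.05 above the unit
#' baseline (tracks differ threefold in brightness, so the faintest are
#' easily obscured by noise), and noise calibrated to a signal-to-noise
#' ratio of 1.4.
#'
#' @inheritParams uniSimConfig
#' @param nTracks number of particles per movie.
#' @param vMax maximum speed (px/frame).
#' @param velocityNoiseRange interval the per-movie jitter half-width is
#'   drawn from (px/frame).
#' @param switchProbRange interval the per-movie stationary/moving switch
#'   probability is drawn from (per frame).
#' @param flipProbRange interval the per-movie velocity sign-flip
#'   probability is drawn from (per frame).
#' @param lifetimeRate exponential lifetime rate per frame.
#' @param sizeRange interval particle PSF FWHMs are drawn from (px).
#' @param amplitudeRange interval particle peak amplitudes are drawn from.
#' @return a configuration list.
#' @export
biSimConfig <- function(pathLength = 300L, nFrames = 300L, nTracks = 15L,
                        vMax = 3, velocityNoiseRange = c(0, 1.5),
                        switchProbRange = c(0, 0.1),
                        flipProbRange = c(0, 0.1), lifetimeRate = 0.001,
                        sizeRange = c(1, 6), amplitudeRange = c(0.35, 1.05),
                        gapRate = 0.05, gapMeanLen = 2, maxGapLen = 6L,
                        targetSNR = 1.4, movieWidth = 20L) {
  stopifnot(pathLength >= 1, nFrames >= 1, nTracks >= 0, vMax > 0,
            all(switchProbRange >= 0), all(switchProbRange <= 0.1),
            all(flipProbRange >= 0), all(flipProbRange <= 0.1),
            all(velocityNoiseRange >= 0), all(velocityNoiseRange <= 1.5),
            lifetimeRate > 0, maxGapLen >= 1)
  list(mode = "bi", pathLength = as.integer(pathLength),
       nFrames = as.integer(nFrames), nTracks = as.integer(nTracks),
       vMax = vMax, velocityNoiseRange = velocityNoiseRange,
       switchProbRange = switchProbRange, flipProbRange = flipProbRange,
       lifetimeRate = lifetimeRate, sizeRange = sizeRange,
       amplitudeRange = amplitudeRange, gapRate = gapRate,
       gapMeanLen = gapMeanLen, maxGapLen = as.integer(maxGapLen),
       targetSNR = targetSNR, movieWidth = as.integer(movieWidth))
}

#' Assign interior signal gaps to a ground-truth track
#'
#' Marks interior runs of points invisible. Gap lengths are exponential
#' with mean \code{gapMeanLen}, rounded up and clipped to
#' \code{maxGapLen}; the expected number of gaps is \code{gapRate} per
#' track point. The first and last point always stay visible, and a gap
#' placement that would merge with an existing gap into a run longer than
#' \code{maxGapLen} is skipped, so every maximal invisible run has length
#' 1..maxGapLen. Ground-truth positions are unchanged; tracks with fewer
#' than 3 points are returned unchanged.
#'
#' @param track data.frame with columns frame, position and (optionally)
#'   visible.
#' @param gapRate expected gaps per track point.
#' @param gapMeanLen mean exponential gap length (frames).
#' @param maxGapLen maximum gap length (frames).
#' @return the track with an updated logical \code{visible} column.
#' @examples
#' tr <- data.frame(frame = 0:19, position = 0:19)
#' set.seed(1)
#' tr <- assignGaps(tr, gapRate = 0.1, gapMeanLen = 2, maxGapLen = 6)
#' @export
assignGaps <- function(track, gapRate, gapMeanLen, maxGapLen) {
  n <- nrow(track)
  if (is.null(track$visible)) track$visible <- rep(TRUE, n)
  if (n < 3 || gapRate <= 0) return(track)
  vis <- track$visible
  nGaps <- rpois(1, gapRate * n)
  for (g in seq_len(nGaps)) {
    len <- min(max(1L, as.integer(ceiling(rexp(1, 1 / gapMeanLen)))),
               as.integer(maxGapLen))
    if (len > n - 2) next
    start <- sample.int(n - 1 - len, 1) + 1L  # interior: 2..(n-len)
    cand <- vis
    cand[start:(start + len - 1)] <- FALSE
    r <- rle(!cand)
    if (max(r$lengths[r$values]) <= maxGapLen) vis <- cand
  }
  track$visible <- vis
  track
}

#' Measure the signal-to-noise ratio of an image
#'
#' The SNR convention used throughout: mean intensity over signal pixels
#' divided by mean intensity over background pixels.
#'
#' @param image numeric matrix.
#' @param signalMask logical matrix of the same shape; TRUE marks signal.
#' @return the intensity ratio.
#' @examples
#' img <- matrix(1, 4, 4); img[1, ] <- 2
#' measureSNR(img, img > 1)  # 2
#' @export
measureSNR <- function(image, signalMask) {
  image <- kymoPixels(image)
  stopifnot(identical(dim(image), dim(signalMask)))
  if (!any(signalMask) || all(signalMask))
    stop("SNR undefined: signal mask is empty or covers the whole image")
  mean(image[signalMask]) / mean(image[!signalMask])
}

# Noiseless signal rendering: every visible point contributes a 1D
# Gaussian profile of the track's PSF (FWHM -> sigma = FWHM/2.355) along
# the path, on a unit baseline. Returns the baseline+signal matrix and the
# signal mask (noiseless added signal > 0.05).
.render_signal <- function(tracks, nFrames, pathLength) {
  S <- matrix(0, nFrames, pathLength)
  if (nrow(tracks)) {
    vis <- tracks[tracks$visible, , drop = FALSE]
    for (k in seq_len(nrow(vis))) {
      sg <- vis$psf[k] / 2.355
      x <- vis$position[k]
      j0 <- max(0L, floor(x - 4 * sg)); j1 <- min(pathLength - 1L, ceiling(x + 4 * sg))
      if (j0 > j1) next
      j <- j0:j1
      r <- vis$frame[k] + 1L
      S[r, j + 1L] <- S[r, j + 1L] + vis$amplitude[k] * exp(-(j - x)^2 / (2 * sg^2))
    }
  }
  list(signal = S, mask = S > 0.05)
}

# Expected pixel intensity after adding N(0, sigma) noise to value c and
# clipping at zero: E[max(c + N, 0)] = c*pnorm(c/s) + s*dnorm(c/s).
.clip_mean <- function(cvals, sigma) {
  if (sigma <= 0) return(pmax(cvals, 0))
  cvals * pnorm(cvals / sigma) + sigma * dnorm(cvals / sigma)
}

# Calibrate the noise sigma so the expected SNR of the clipped noisy
# render equals the target. The expectation is computed in closed form
# from the noiseless image, so the calibration is deterministic.
.calibrate_sigma <- function(signal, mask, target) {
  if (!any(mask)) return(0.1)  # no signal: SNR undefined, any noise level
  sig <- signal[mask] + 1
  bg <- signal[!mask] + 1
  f <- function(s) mean(.clip_mean(sig, s)) / mean(.clip_mean(bg, s)) - target
  if (f(0) <= 0) return(0)        # noiseless SNR already at/below target
  if (f(30) > 0) return(30)
  uniroot(f, c(0, 30), tol = 1e-6)$root
}

.render_noisy <- function(signal, sigma) {
  pmax(signal + 1 + matrix(rnorm(length(signal), 0, sigma),
                           nrow(signal), ncol(signal)), 0)
}

# Transverse movie: same longitudinal profiles, modulated by a transverse
# Gaussian centred on the path (middle row of the movie).
.render_movie <- function(tracks, nFrames, pathLength, movieWidth, sigma) {
  mov <- array(0, dim = c(movieWidth, pathLength, nFrames))
  centre <- (movieWidth - 1) / 2
  if (nrow(tracks)) {
    vis <- tracks[tracks$visible, , drop = FALSE]
    tprof <- function(sg) exp(-((0:(movieWidth - 1)) - centre)^2 / (2 * sg^2))
    for (k in seq_len(nrow(vis))) {
      sg <- vis$psf[k] / 2.355
      x <- vis$position[k]
      j0 <- max(0L, floor(x - 4 * sg)); j1 <- min(pathLength - 1L, ceiling(x + 4 * sg))
      if (j0 > j1) next
      j <- j0:j1
      prof <- vis$amplitude[k] * exp(-(j - x)^2 / (2 * sg^2))
      f <- vis$frame[k] + 1L
      mov[, j + 1L, f] <- mov[, j + 1L, f] + tprof(sg) %o% prof
    }
  }
  pmax(mov + 1 + array(rnorm(length(mov), 0, sigma), dim = dim(mov)), 0)
}

# Remove tracks whose rounded position coincides with another track's at
# every frame of their own lifetime (fully occluded, invisible in the
# render as an individual object).
.occlusion_filter <- function(tracks) {
  if (length(unique(tracks$id)) < 2) return(tracks)
  per <- split(tracks, tracks$id)
  ids <- names(per)
  drop <- setNames(logical(length(ids)), ids)
  for (a in seq_along(ids)) {
    ta <- per[[a]]
    key_a <- paste(ta$frame, round(ta$position))
    for (b in seq_along(ids)) {
      if (a == b || drop[b]) next
      tb <- per[[b]]
      if (nrow(tb) < nrow(ta)) next
      if (all(key_a %in% paste(tb$frame, round(tb$position)))) {
        drop[a] <- TRUE
        break
      }
    }
  }
  tracks[!(as.character(tracks$id) %in% names(drop)[drop]), , drop = FALSE]
}

.finalize_sample <- function(tracks, cfg, seed, renderMovie) {
  rs <- .render_signal(tracks, cfg$nFrames, cfg$pathLength)
  sigma <- .calibrate_sigma(rs$signal, rs$mask, cfg$targetSNR)
  kymo <- .render_noisy(rs$signal, sigma)
  snr <- if (any(rs$mask) && !all(rs$mask)) measureSNR(kymo, rs$mask) else NA_real_
  movie <- if (renderMovie)
    .render_movie(tracks, cfg$nFrames, cfg$pathLength, cfg$movieWidth, sigma)
  else NULL
  new("SyntheticSample", kymograph = Kymograph(kymo), movie = movie,
      tracks = tracks, config = cfg, seed = as.integer(seed),
      measuredSNR = snr, noiseSigma = sigma, signalMask = rs$mask)
}

.empty_tracks <- function(extra = character()) {
  base <- data.frame(id = integer(), frame = integer(), position = numeric(),
                     visible = logical(), amplitude = numeric(),
                     psf = numeric())
  for (e in extra) base[[e]] <- logical()
  base
}

#' Simulate a unidirectional particle movie
#'
#' Particles move with one movie-wide base speed (drawn from
#' \code{speedRange}), a fixed slope sign per particle and small uniform
#' per-frame velocity jitter; lifetimes are exponential; interior signal
#' gaps are assigned per track; fully occluded tracks are removed; the
#' kymograph (and optionally a transverse movie) is rendered with
#' calibrated Gaussian noise. Deterministic given (cfg, seed).
#'
#' @param cfg configuration from \code{\link{uniSimConfig}}.
#' @param seed integer seed.
#' @param renderMovie render the transverse movie as well (slower).
#' @return a \linkS4class{SyntheticSample}.
#' @examples
#' s <- simulateUnidirectional(uniSimConfig(nPerDirection = 3), seed = 1,
#'                             renderMovie = FALSE)
#' measuredSNR(s)
#' @export
simulateUnidirectional <- function(cfg = uniSimConfig(), seed = 1L,
                                   renderMovie = TRUE) {
  stopifnot(identical(cfg$mode, "uni"))
  .with_seed(seed, {
    vBase <- runif(1, cfg$speedRange[1], cfg$speedRange[2])
    n <- 2L * cfg$nPerDirection
    rows <- list()
    for (i in seq_len(n)) {
      sgn <- if (i <= cfg$nPerDirection) 1 else -1
      t0 <- sample.int(cfg$nFrames, 1) - 1L
      x0 <- runif(1, 0, cfg$pathLength)
      life <- 1L + as.integer(floor(rexp(1, cfg$survivalRate)))
      psf <- runif(1, cfg$psfRange[1], cfg$psfRange[2])
      nmax <- min(life, cfg$nFrames - t0)
      jit <- runif(nmax, -cfg$speedNoise, cfg$speedNoise)
      pos <- x0 + cumsum(c(0, sgn * vBase + jit[-1]))
      keep <- pos >= 0 & pos < cfg$pathLength
      if (any(!keep)) pos <- pos[seq_len(which(!keep)[1] - 1)]
      if (length(pos) < 2) next
      tr <- data.frame(id = i, frame = t0 + seq_along(pos) - 1L,
                       position = pos, visible = TRUE, amplitude = cfg$amplitude,
                       psf = psf)
      rows[[length(rows) + 1]] <-
        assignGaps(tr, cfg$gapRate, cfg$gapMeanLen, cfg$maxGapLen)
    }
    tracks <- if (length(rows)) do.call(rbind, rows) else .empty_tracks()
    tracks <- .occlusion_filter(tracks)
    rownames(tracks) <- NULL
    .finalize_sample(tracks, cfg, seed, renderMovie)
  })
}

#' Simulate a bidirectional particle movie
#'
#' Each particle follows a two-state machine: a random initial state
#' (moving or stationary) and initial velocity, per-frame switching
#' between the states with the movie's switch probability, per-frame
#' velocity sign flips with the movie's flip probability, and a per-frame
#' uniform velocity random walk bounded so speed never exceeds
#' \code{vMax}. Lifetimes are exponential; gaps, occlusion removal and
#' rendering are as in the unidirectional simulator. Deterministic given
#' (cfg, seed).
#'
#' @param cfg configuration from \code{\link{biSimConfig}}.
#' @param seed integer seed.
#' @param renderMovie render the transverse movie as well.
#' @return a \linkS4class{SyntheticSample}; the ground-truth table has an
#'   extra logical column \code{moving} (per-frame motion state).
#' @export
simulateBidirectional <- function(cfg = biSimConfig(), seed = 1L,
                                  renderMovie = TRUE) {
  stopifnot(identical(cfg$mode, "bi"))
  .with_seed(seed, {
    vn <- runif(1, cfg$velocityNoiseRange[1], cfg$velocityNoiseRange[2])
    pSwitch <- runif(1, cfg$switchProbRange[1], cfg$switchProbRange[2])
    pFlip <- runif(1, cfg$flipProbRange[1], cfg$flipProbRange[2])
    rows <- list()
    for (i in seq_len(cfg$nTracks)) {
      life <- 1L + as.integer(floor(rexp(1, cfg$lifetimeRate)))
      t0 <- sample.int(cfg$nFrames, 1) - 1L
      x0 <- runif(1, 0, cfg$pathLength)
      psf <- runif(1, cfg$sizeRange[1], cfg$sizeRange[2])
      amp <- runif(1, cfg$amplitudeRange[1], cfg$amplitudeRange[2])
      moving <- runif(1) < 0.5
      v <- runif(1, -cfg$vMax, cfg$vMax)
      nmax <- min(life, cfg$nFrames - t0)
      pos <- numeric(nmax); mv <- logical(nmax)
      pos[1] <- x0; mv[1] <- moving
      nkeep <- 1L
      if (nmax >= 2) for (f in 2:nmax) {
        if (runif(1) < pSwitch) moving <- !moving
        if (runif(1) < pFlip) v <- -v
        v <- max(-cfg$vMax, min(cfg$vMax, v + runif(1, -vn, vn)))
        x <- pos[f - 1] + if (moving) v else 0
        if (x < 0 || x >= cfg$pathLength) break
        pos[f] <- x; mv[f] <- moving; nkeep <- f
      }
      if (nkeep < 2) next
      tr <- data.frame(id = i, frame = t0 + seq_len(nkeep) - 1L,
                       position = pos[seq_len(nkeep)], visible = TRUE,
                       amplitude = amp, psf = psf,
                       moving = mv[seq_len(nkeep)])
      rows[[length(rows) + 1]] <-
        assignGaps(tr, cfg$gapRate, cfg$gapMeanLen, cfg$maxGapLen)
    }
    tracks <- if (length(rows)) do.call(rbind, rows)
              else .empty_tracks("moving")
    tracks <- .occlusion_filter(tracks)
    rownames(tracks) <- NULL
    .finalize_sample(tracks, cfg, seed, renderMovie)
  })
}

#' Render ground-truth tracks into a noisy kymograph
#'
#' Exposes the rendering step on its own: visible points contribute 1D
#' Gaussian profiles (FWHM = the track's psf) on a unit baseline,
#' Gaussian noise of the given sigma is added and intensities are clipped
#' at zero.
#'
#' @param tracks ground-truth table (id, frame, position, visible,
#'   amplitude, psf).
#' @param nFrames,pathLength kymograph dimensions.
#' @param noiseSigma Gaussian noise standard deviation.
#' @return list with elements kymograph (matrix), signalMask (logical
#'   matrix) and signal (noiseless added intensity).
#' @export
renderTracks <- function(tracks, nFrames, pathLength, noiseSigma = 0) {
  rs <- .render_signal(tracks, nFrames, pathLength)
  list(kymograph = .render_noisy(rs$signal, noiseSigma),
       signalMask = rs$mask, signal = rs$signal)
}
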