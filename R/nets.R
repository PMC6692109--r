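# Network modules: a shared U-Net core with four heads (kymograph
# classification, unidirectional segmentation, bidirectional segmentation,
# branch-point decision), training-set construction from simulated data,
# augmentation, and the training loop.

#' Leaky rectifier
#'
#' \code{leakyReLU(x) = max(x, 0) - 0.1 * max(-x, 0)}: identity for
#' positive inputs, slope 0.1 below zero.
#'
#' @param x numeric vector/matrix.
#' @return same shape as x.
#' @examples
#' leakyReLU(c(-1, 0, 2))  # -0.1 0 2
#' @export
leakyReLU <- function(x) pmax(x, 0) - 0.1 * pmax(-x, 0)

#' Per-entry cross entropy
#'
#' \code{CE(t, o) = -(t ln o + (1 - t) ln(1 - o))}, averaged over all
#' entries; outputs are clipped away from 0 and 1 before the logs.
#'
#' @param t target(s) in [0, 1].
#' @param o output(s) in (0, 1).
#' @param eps clipping margin.
#' @return mean cross entropy (non-negative scalar).
#' @examples
#' crossEntropy(1, 0.5)  # log(2)
#' @export
crossEntropy <- function(t, o, eps = 1e-7) {
  o <- pmin(pmax(o, eps), 1 - eps)
  mean(-(t * log(o) + (1 - t) * log(1 - o)))
}

#' Build a network module
#'
#' All four module kinds share a depth-4 U-Net core whose feature widths
#' are \code{64 * widthMultiplier} at the top level doubling to
#' \code{1024 * widthMultiplier} at the bottom. Heads: "class" takes one
#' 64 x 64 image and emits two class probabilities (unidirectional,
#' bidirectional) that sum to 1; "uniseg" takes one image (dimensions
#' multiples of 16; other sizes are resized internally and restored) and
#' emits two trackness maps in [0, 1] (positive- and negative-slope
#' tracks); "biseg" emits one trackness map; "decision" takes three
#' 48 x 48 inputs (raw crop, full-skeleton crop, current-track crop) and
#' emits one 48 x 48 trackness map. The decision module applies 50 %
#' dropout to the full-skeleton input and 5 % to the current-track input
#' during training; the segmentation modules use dropout along the
#' contracting path.
#'
#' @param kind "class", "uniseg", "biseg" or "decision".
#' @param widthMultiplier scales all feature counts (1 = the full-size
#'   reference 64..1024; small fractions train on a desk CPU).
#' @param depth number of down/up-sampling levels.
#' @param dropout contracting-path dropout rate for segmentation modules.
#' @param seed weight-initialisation seed.
#' @return a \linkS4class{UNetModule}.
#' @examples
#' m <- buildModule("biseg", widthMultiplier = 1 / 32)
#' @export
buildModule <- function(kind = c("uniseg", "biseg", "class", "decision"),
                        widthMultiplier = 1, depth = 4L, dropout = 0.15,
                        seed = 1L) {
  kind <- match.arg(kind)
  base <- max(1L, as.integer(round(64 * widthMultiplier)))
  spec <- switch(kind,
    class = list(cin = 1L, cout = 2L, head = 1L, de = 0, di = 0),
    uniseg = list(cin = 1L, cout = 2L, head = 0L, de = dropout, di = 0),
    biseg = list(cin = 1L, cout = 1L, head = 0L, de = dropout, di = 0),
    decision = list(cin = 3L, cout = 1L, head = 0L, de = 0,
                    di = c(0, 0.5, 0.05)))
  ptr <- cpp_unet_create(spec$cin, spec$cout, base, as.integer(depth),
                         spec$head, spec$de, spec$di, as.integer(seed))
  new("UNetModule", ptr = ptr, kind = kind,
      config = list(base = base, depth = as.integer(depth),
                    cin = spec$cin, cout = spec$cout, seed = as.integer(seed),
                    widthMultiplier = widthMultiplier, dropout = dropout))
}

#' @describeIn buildModule number of trainable parameters (batch-norm
#'   scale/shift included, running statistics excluded).
#' @param module a \linkS4class{UNetModule}.
#' @export
nParameters <- function(module) cpp_unet_nparams(module@ptr)

#' Rescale an image to [0, 1]
#'
#' Robust contrast normalisation used for all network inputs and the
#' wavelet baseline: the 1st and 99th intensity percentiles map to 0 and
#' 1 and values outside are clipped, so a few extreme noise pixels do not
#' compress the usable dynamic range.
#'
#' @param x numeric matrix.
#' @return matrix with values in [0, 1] (all-constant input maps to 0).
#' @export
normalizeImage <- function(x) {
  x <- kymoPixels(x)
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (diff(q) < 1e-12) {
    rg <- range(x)
    if (diff(rg) < 1e-12) return(x * 0)
    q <- rg
  }
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

.resize16 <- function(m) {
  d <- dim(m)
  d2 <- pmax(16L, as.integer(ceiling(d / 16) * 16))
  if (all(d == d2)) return(list(m = m, orig = d))
  list(m = EBImage::resize(m, w = d2[1], h = d2[2]), orig = d)
}

.stack_batch <- function(items) {
  # items: list of H x W x C arrays (or matrices, C = 1)
  a1 <- items[[1]]
  if (is.matrix(a1)) items <- lapply(items, function(m) array(m, c(dim(m), 1)))
  d <- dim(items[[1]])
  x <- array(0, c(d, length(items)))
  for (i in seq_along(items)) x[, , , i] <- items[[i]]
  x
}

#' Run a module on its input
#'
#' Handles normalisation and the multiple-of-16 size contract: inputs of
#' other sizes are resized internally and the output map restored to the
#' input size.
#'
#' @param module a \linkS4class{UNetModule}.
#' @param input for "class", "uniseg", "biseg": a kymograph (matrix or
#'   \linkS4class{Kymograph}); for "decision": a 48 x 48 x 3 array.
#' @return "class": named probability vector (uni, bi); segmentation: an
#'   H x W x C trackness array in [0, 1] (C = 2 for "uniseg", else a
#'   matrix); "decision": a 48 x 48 trackness matrix.
#' @export
predictMap <- function(module, input) {
  kind <- module@kind
  if (kind == "class") {
    m <- normalizeImage(input)
    m <- EBImage::resize(m, w = 64, h = 64)
    p <- cpp_unet_forward(module@ptr, .stack_batch(list(m)))
    return(c(uni = p[1, 1], bi = p[1, 2]))
  }
  if (kind == "decision") {
    stopifnot(length(dim(input)) == 3, dim(input)[3] == 3)
    o <- cpp_unet_forward(module@ptr, .stack_batch(list(input)))
    return(o[, , 1, 1])
  }
  m <- normalizeImage(input)
  rs <- .resize16(m)
  o <- cpp_unet_forward(module@ptr, .stack_batch(list(rs$m)))
  cout <- dim(o)[3]
  maps <- lapply(seq_len(cout), function(ch) {
    mp <- o[, , ch, 1]
    if (!all(dim(mp) == rs$orig))
      mp <- EBImage::resize(mp, w = rs$orig[1], h = rs$orig[2])
    pmin(pmax(mp, 0), 1)
  })
  if (cout == 1) return(maps[[1]])
  array(unlist(maps), c(rs$orig, cout))
}

# ---- training-set construction -------------------------------------------

# Rasterize tracks as connected lines: consecutive frames are joined by
# interpolated pixels (a particle moving several px/frame sweeps across
# columns within the frame step), so the raster is 8-connected the way
# the rendered kymograph line is. Non-consecutive frames (e.g. missing
# frames in a prediction) are not bridged.
.render_binary_tracks <- function(points, dims) {
  m <- matrix(0, dims[1], dims[2])
  if (!nrow(points)) return(m)
  clampc <- function(x) pmin(pmax(round(x), 0), dims[2] - 1) + 1L
  for (tr in split(points, points$id)) {
    tr <- tr[order(tr$frame), ]
    r <- tr$frame + 1L
    ok <- r >= 1 & r <= dims[1]
    m[cbind(r[ok], clampc(tr$position[ok]))] <- 1
    if (nrow(tr) < 2) next
    for (k in seq_len(nrow(tr) - 1)) {
      if (tr$frame[k + 1] != tr$frame[k] + 1) next
      dx <- tr$position[k + 1] - tr$position[k]
      nst <- max(2L, as.integer(ceiling(abs(dx))) + 1L)
      tt <- seq(0, 1, length.out = nst)
      rr <- round(tr$frame[k] + tt) + 1L
      cc <- clampc(tr$position[k] + tt * dx)
      okk <- rr >= 1 & rr <= dims[1]
      m[cbind(rr[okk], cc[okk])] <- 1
    }
  }
  m
}

.track_direction <- function(tr) sign(tr$position[nrow(tr)] - tr$position[1])

# widen a binary line map by one pixel along the position axis only:
# thick targets stabilise training against foreground sparsity without
# thickening along time (which would shift the optimal binarization
# threshold and blur crossings)
.dilate_pos <- function(m) {
  m2 <- m
  m2[, -1] <- pmax(m2[, -1], m[, -ncol(m)])
  m2[, -ncol(m)] <- pmax(m2[, -ncol(m)], m[, -1])
  m2
}

#' Build a segmentation training set from simulations
#'
#' Each item pairs a normalised noisy kymograph with its binary
#' ground-truth track map(s), rendered from all ground-truth points
#' (points hidden inside artificial signal gaps included, so the module
#' learns to bridge gaps) and widened by one pixel along the position
#' axis — the
#' foreground is otherwise so sparse that desk-scale training
#' under-commits, and tracing re-thins the predicted maps to one pixel
#' anyway. Unidirectional items carry two target channels
#' (positive-slope tracks, negative-slope tracks); bidirectional items
#' carry one.
#'
#' @param mode "uni" or "bi".
#' @param n number of simulated kymographs.
#' @param cfg simulator configuration (defaults to the mode's default).
#' @param seed base seed; sample i uses seed + i.
#' @return list of items with elements kymo (matrix) and target
#'   (H x W x C array).
#' @export
makeSegTrainingSet <- function(mode = c("uni", "bi"), n = 20,
                               cfg = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cfg))
    cfg <- if (mode == "uni") uniSimConfig() else biSimConfig(nTracks = 30L)
  lapply(seq_len(n), function(i) {
    s <- if (mode == "uni")
      simulateUnidirectional(cfg, seed = seed + i, renderMovie = FALSE)
    else simulateBidirectional(cfg, seed = seed + i, renderMovie = FALSE)
    dims <- dim(kymoPixels(s@kymograph))
    gt <- s@tracks
    if (mode == "uni") {
      dirs <- vapply(split(gt, gt$id), .track_direction, numeric(1))
      posIds <- names(dirs)[dirs > 0]
      tgt <- array(0, c(dims, 2))
      tgt[, , 1] <- .dilate_pos(.render_binary_tracks(
        gt[as.character(gt$id) %in% posIds, ], dims))
      tgt[, , 2] <- .dilate_pos(.render_binary_tracks(
        gt[!(as.character(gt$id) %in% posIds), ], dims))
    } else {
      tgt <- array(.dilate_pos(.render_binary_tracks(gt, dims)),
                   c(dims, 1))
    }
    list(kymo = normalizeImage(kymoPixels(s@kymograph)), target = tgt)
  })
}

#' Build a classification training set from simulations
#'
#' Kymographs are resized to 64 x 64; labels are one-hot
#' (unidirectional, bidirectional).
#'
#' @param nPerClass kymographs per class.
#' @param cfgUni,cfgBi simulator configurations.
#' @param seed base seed.
#' @return list of items with elements img (64 x 64) and label (1 = uni,
#'   2 = bi).
#' @export
makeClassTrainingSet <- function(nPerClass = 30, cfgUni = uniSimConfig(),
                                 cfgBi = biSimConfig(nTracks = 30L),
                                 seed = 1L) {
  items <- list()
  for (i in seq_len(nPerClass)) {
    su <- simulateUnidirectional(cfgUni, seed = seed + i, renderMovie = FALSE)
    sb <- simulateBidirectional(cfgBi, seed = seed + 10000 + i,
                                renderMovie = FALSE)
    items[[2 * i - 1]] <- list(
      img = EBImage::resize(normalizeImage(kymoPixels(su@kymograph)),
                            w = 64, h = 64), label = 1L)
    items[[2 * i]] <- list(
      img = EBImage::resize(normalizeImage(kymoPixels(sb@kymograph)),
                            w = 64, h = 64), label = 2L)
  }
  items
}

.crop_pad <- function(m, r0, c0, h, w) {
  # 0-based top-left corner; zero padding outside the image
  out <- matrix(0, h, w)
  rr <- (r0 + 1):(r0 + h); cc <- (c0 + 1):(c0 + w)
  okr <- rr >= 1 & rr <= nrow(m); okc <- cc >= 1 & cc <= ncol(m)
  out[okr, okc] <- m[rr[okr], cc[okc]]
  out
}

#' Build a decision-module training set
#'
#' Ground-truth tracks are rendered as 1-px binary maps and their union
#' thinned; branch points are skeleton pixels with 3 or more neighbours.
#' Every track segment that ends within 3 px of a branch point yields one
#' sample: a 48 x 48 raw-kymograph crop, the full-skeleton crop, the
#' upstream-segment crop with its end at the anchor pixel (24, 24)
#' 0-based, and the downstream segment as the target. Crops near borders
#' are zero padded.
#'
#' @param sample a bidirectional \linkS4class{SyntheticSample}, or NULL if
#'   kymo and gtTracks are given.
#' @param kymo kymograph matrix (used for the raw crop).
#' @param gtTracks ground-truth \linkS4class{KymoTracks} or point table.
#' @param cropSize crop side length.
#' @return list of samples with elements inputs (48 x 48 x 3 array:
#'   raw, full skeleton, upstream segment), target (48 x 48 matrix),
#'   anchor (0-based (row, col) of the branch-side segment end).
#' @export
makeDecisionTrainingSet <- function(sample = NULL, kymo = NULL,
                                    gtTracks = NULL, cropSize = 48L) {
  if (!is.null(sample)) {
    kymo <- kymoPixels(sample@kymograph)
    gtTracks <- sample@tracks
  }
  pts <- if (is(gtTracks, "KymoTracks")) as.data.frame(gtTracks) else gtTracks
  dims <- dim(kymo)
  full <- cpp_thin(.int_mat(.render_binary_tracks(pts, dims)))
  ncnt <- cpp_neighbor_count(full)
  bp <- which(ncnt >= 3 & full > 0, arr.ind = TRUE) - 1L  # 0-based
  if (nrow(bp) == 0) return(list())
  half <- cropSize %/% 2
  rawn <- normalizeImage(kymo)
  fullM <- matrix(as.numeric(full > 0), dims[1], dims[2])
  out <- list()
  for (tr in split(pts, pts$id)) {
    r <- tr$frame
    c <- pmin(pmax(round(tr$position), 0), dims[2] - 1)
    # indices along the track that touch a branch point (Euclidean <= 3)
    touches <- vapply(seq_along(r), function(k)
      any((bp[, 1] - r[k])^2 + (bp[, 2] - c[k])^2 <= 9), logical(1))
    # segment ends: last touching index of each contact run
    runs <- rle(touches)
    ends <- cumsum(runs$lengths)
    cut <- ends[runs$values]          # indices where a contact run ends
    cut <- cut[cut < length(r)]       # need a downstream part
    prev <- 0L
    for (k in cut) {
      ar <- r[k]; ac <- c[k]
      r0 <- ar - half; c0 <- ac - half
      seg <- matrix(0, dims[1], dims[2])
      up <- (prev + 1):k
      seg[cbind(r[up] + 1, c[up] + 1)] <- 1
      down <- matrix(0, dims[1], dims[2])
      dn <- (k + 1):length(r)
      down[cbind(r[dn] + 1, c[dn] + 1)] <- 1
      inputs <- array(0, c(cropSize, cropSize, 3))
      inputs[, , 1] <- .crop_pad(rawn, r0, c0, cropSize, cropSize)
      inputs[, , 2] <- .crop_pad(fullM, r0, c0, cropSize, cropSize)
      inputs[, , 3] <- .crop_pad(seg, r0, c0, cropSize, cropSize)
      out[[length(out) + 1]] <- list(
        inputs = inputs,
        target = .crop_pad(down, r0, c0, cropSize, cropSize),
        anchor = c(ar, ac))
      prev <- k
    }
  }
  out
}

.int_mat <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# ---- augmentation ---------------------------------------------------------

.aug_noise <- function(m) {
  if (runif(1) < 0.5)
    m <- m + matrix(rnorm(length(m), 0, runif(1, 0, 0.08)), nrow(m))
  if (runif(1) < 0.5)
    m <- m + matrix(runif(length(m), 0, runif(1, 0, 0.1)), nrow(m))
  if (runif(1) < 0.5) {
    gr <- runif(2, -0.15, 0.15)
    m <- m + outer(seq(0, 1, length.out = nrow(m)) * gr[1],
                   seq(0, 1, length.out = ncol(m)) * gr[2], "+") / 2
  }
  m
}

.aug_seg <- function(img, tgt, swapOnFlip) {
  if (runif(1) < 0.5) {  # reflect along position axis
    img <- img[, ncol(img):1]
    tgt <- tgt[, ncol(img):1, , drop = FALSE]
    if (swapOnFlip && dim(tgt)[3] == 2) tgt <- tgt[, , 2:1, drop = FALSE]
  }
  if (runif(1) < 0.5) {  # reflect along time axis
    img <- img[nrow(img):1, ]
    tgt <- tgt[nrow(img):1, , , drop = FALSE]
    if (swapOnFlip && dim(tgt)[3] == 2) tgt <- tgt[, , 2:1, drop = FALSE]
  }
  list(img = .aug_noise(img), tgt = tgt)
}

.aug_class <- function(img) {
  if (runif(1) < 0.5) img <- img[, ncol(img):1]
  if (runif(1) < 0.5) img <- img[nrow(img):1, ]
  if (runif(1) < 0.25) img <- 1 - img  # colour negation
  .aug_noise(img)
}

.aug_decision <- function(inputs, target) {
  inputs[, , 1] <- .aug_noise(inputs[, , 1])
  for (ch in 2:3)  # random pixel deletion emulates thinning artefacts
    if (runif(1) < 0.5) {
      m <- inputs[, , ch]
      m[runif(length(m)) < 0.1] <- 0
      inputs[, , ch] <- m
    }
  list(inputs = inputs, target = target)
}

# ---- training loop --------------------------------------------------------

.rand_crop <- function(img, tgt, ch, cw) {
  r0 <- sample.int(max(nrow(img) - ch + 1, 1), 1) - 1L
  c0 <- sample.int(max(ncol(img) - cw + 1, 1), 1) - 1L
  list(img = .crop_pad(img, r0, c0, ch, cw),
       tgt = array(vapply(seq_len(dim(tgt)[3]), function(k)
         .crop_pad(tgt[, , k], r0, c0, ch, cw), matrix(0, ch, cw)),
         c(ch, cw, dim(tgt)[3])))
}

#' Train a network module
#'
#' Splits the data 95/5 into training and validation, then runs Adam
#' (initial learning rate \code{lr}) over randomly augmented, randomly
#' cropped batches with a step learning-rate decay (factor 0.5 at
#' \code{schedulePoint} batches). The checkpoint with the best validation
#' score is kept. Crop sizes follow the module kind: 64 x 64 (class),
#' 128 x 80 (segmentation), 48 x 48 (decision); class batches are drawn
#' balanced (half unidirectional, half bidirectional).
#'
#' @param module a \linkS4class{UNetModule} (updated in place).
#' @param data training items from the matching \code{make*TrainingSet}.
#' @param nBatches number of batches.
#' @param batchSize batch size (defaults per kind: 50 class/decision, 20
#'   segmentation).
#' @param lr initial learning rate.
#' @param schedulePoint batch index after which the learning rate is
#'   halved (defaults: 4000 uniseg, 3000 biseg, 8000 decision, scaled
#'   proportionally when nBatches is smaller).
#' @param valFrac validation fraction.
#' @param evalEvery batches between validation evaluations.
#' @param augment apply random augmentation.
#' @param seed RNG seed for batching/augmentation.
#' @param stopAtZeroValError ("class" only) stop once the validation
#'   error rate has been 0 at this many consecutive evaluations.
#' @return invisibly, a data.frame history (batch, loss, valLoss,
#'   valError).
#' @export
trainModule <- function(module, data, nBatches = 200L, batchSize = NULL,
                        lr = 1e-3, schedulePoint = NULL, valFrac = 0.05,
                        evalEvery = 10L, augment = TRUE, seed = 1L,
                        stopAtZeroValError = 2L) {
  kind <- module@kind
  if (is.null(batchSize))
    batchSize <- switch(kind, class = 50L, decision = 50L, 20L)
  if (is.null(schedulePoint)) {
    ref <- switch(kind, uniseg = 4000, biseg = 3000, decision = 8000,
                  class = 4000)
    refTotal <- switch(kind, decision = 16000, 8000)
    schedulePoint <- max(1L, as.integer(round(nBatches * ref / refTotal)))
  }
  stopifnot(length(data) >= 2)
  if (kind != "class") {
    # initialise the head bias at the base-rate logit so the first
    # hundreds of batches refine structure instead of drifting the
    # output mean toward the foreground fraction
    pbar <- mean(vapply(data[seq_len(min(8, length(data)))],
                        function(it) mean(it$target), numeric(1)))
    pbar <- min(max(pbar, 1e-4), 1 - 1e-4)
    st <- cpp_unet_state(module@ptr)
    st[[length(st)]][] <- log(pbar / (1 - pbar))
    cpp_unet_set_state(module@ptr, st)
  }
  .with_seed(seed, {
    nVal <- max(1L, as.integer(round(length(data) * valFrac)))
    valIdx <- sample.int(length(data), nVal)
    trIdx <- setdiff(seq_along(data), valIdx)
    if (kind == "class") {
      labs <- vapply(data, `[[`, integer(1), "label")
      trUni <- trIdx[labs[trIdx] == 1L]; trBi <- trIdx[labs[trIdx] == 2L]
    }
    hist <- data.frame(batch = integer(), loss = numeric(),
                       valLoss = numeric(), valError = numeric())
    best <- Inf; bestState <- NULL; zeroRuns <- 0L
    valBatch <- .make_eval_batch(kind, data[valIdx])
    for (b in seq_len(nBatches)) {
      lrb <- lr * if (b < schedulePoint) 1 else 0.5
      samp <- function(v, k) v[sample.int(length(v), k, replace = TRUE)]
      if (kind == "class") {
        idx <- c(samp(trUni, batchSize %/% 2), samp(trBi, batchSize %/% 2))
      } else {
        idx <- samp(trIdx, batchSize)
      }
      ba <- .make_train_batch(kind, data[idx], augment)
      loss <- cpp_unet_train_batch(module@ptr, ba$x, ba$t, lrb)
      if (b %% evalEvery == 0 || b == nBatches) {
        ev <- .eval_module(module, kind, valBatch)
        hist <- rbind(hist, data.frame(batch = b, loss = loss,
                                       valLoss = ev$loss,
                                       valError = ev$error))
        score <- if (kind == "class") ev$error + ev$loss * 1e-3 else ev$loss
        if (score < best) {
          best <- score
          bestState <- cpp_unet_state(module@ptr)
        }
        if (kind == "class") {
          zeroRuns <- if (ev$error == 0) zeroRuns + 1L else 0L
          if (zeroRuns >= stopAtZeroValError) break
        }
      }
      if (!is.finite(loss)) stop("training diverged (non-finite loss)")
    }
    if (!is.null(bestState)) cpp_unet_set_state(module@ptr, bestState)
    invisible(hist)
  })
}

.make_train_batch <- function(kind, items, augment) {
  if (kind == "class") {
    imgs <- lapply(items, function(it)
      if (augment) .aug_class(it$img) else it$img)
    t <- t(vapply(items, function(it)
      as.numeric(it$label == 1:2), numeric(2)))
    return(list(x = .stack_batch(imgs), t = t))
  }
  if (kind == "decision") {
    xs <- list(); ts <- list()
    for (it in items) {
      a <- if (augment) .aug_decision(it$inputs, it$target)
           else list(inputs = it$inputs, target = it$target)
      xs[[length(xs) + 1]] <- a$inputs
      ts[[length(ts) + 1]] <- a$target
    }
    return(list(x = .stack_batch(xs), t = .stack_batch(ts)))
  }
  xs <- list(); ts <- list()
  for (it in items) {
    a <- if (augment) .aug_seg(it$kymo, it$target, swapOnFlip = TRUE)
         else list(img = it$kymo, tgt = it$target)
    cr <- .rand_crop(a$img, a$tgt, 128L, 80L)
    xs[[length(xs) + 1]] <- cr$img
    ts[[length(ts) + 1]] <- cr$tgt
  }
  list(x = .stack_batch(xs), t = .stack_batch(ts))
}

.make_eval_batch <- function(kind, items) {
  if (kind == "class") {
    return(list(x = .stack_batch(lapply(items, `[[`, "img")),
                t = t(vapply(items, function(it)
                  as.numeric(it$label == 1:2), numeric(2))),
                labels = vapply(items, `[[`, integer(1), "label")))
  }
  if (kind == "decision") {
    return(list(x = .stack_batch(lapply(items, `[[`, "inputs")),
                t = .stack_batch(lapply(items, `[[`, "target"))))
  }
  xs <- list(); ts <- list()
  for (it in items) {  # centre crop for a stable validation score
    r0 <- max(0L, (nrow(it$kymo) - 128L) %/% 2)
    c0 <- max(0L, (ncol(it$kymo) - 80L) %/% 2)
    xs[[length(xs) + 1]] <- .crop_pad(it$kymo, r0, c0, 128L, 80L)
    ts[[length(ts) + 1]] <- array(vapply(seq_len(dim(it$target)[3]),
      function(k) .crop_pad(it$target[, , k], r0, c0, 128L, 80L),
      matrix(0, 128, 80)), c(128L, 80L, dim(it$target)[3]))
  }
  list(x = .stack_batch(xs), t = .stack_batch(ts))
}

.eval_module <- function(module, kind, valBatch) {
  loss <- cpp_unet_eval_loss(module@ptr, valBatch$x, valBatch$t)
  err <- NA_real_
  if (kind == "class") {
    p <- cpp_unet_forward(module@ptr, valBatch$x)
    err <- mean((p[, 1] < p[, 2]) + 1L != valBatch$labels)
  }
  list(loss = loss, error = err)
}

#' Save / load a trained module
#'
#' Stores the weights together with the architecture configuration.
#'
#' @param module a \linkS4class{UNetModule}.
#' @param path file path (.rds).
#' @return \code{loadModule} returns the restored module.
#' @export
saveModule <- function(module, path) {
  saveRDS(list(kind = module@kind, config = module@config,
               state = cpp_unet_state(module@ptr)), path)
  invisible(path)
}

#' @rdname saveModule
#' @export
loadModule <- function(path) {
  obj <- readRDS(path)
  m <- buildModule(obj$kind, widthMultiplier = obj$config$widthMultiplier,
                   depth = obj$config$depth, dropout = obj$config$dropout,
                   seed = obj$config$seed)
  cpp_unet_set_state(m@ptr, obj$state)
  m
}
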