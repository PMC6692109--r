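# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops over tracks, frames and pixels) and
# never call the package's vectorised metric code.

# tiny simulator configs for fast unit tests
tinyUniCfg <- function(...) {
  args <- list(pathLength = 80L, nFrames = 80L, movieWidth = 10L,
               nPerDirection = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(uniSimConfig, args)
}
tinyBiCfg <- function(...) {
  args <- list(pathLength = 80L, nFrames = 80L, movieWidth = 10L,
               nTracks = 5L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(biSimConfig, args)
}

# a straight-line track table
lineTrack <- function(id, frames, x0, v) {
  data.frame(id = id, frame = frames, position = x0 + v * seq_along(frames) - v)
}

# random small track sets for metric oracle comparisons
randomTrackSet <- function(nTracks, nFrames, pathLength, rng) {
  if (nTracks == 0)
    return(data.frame(id = integer(), frame = integer(),
                      position = numeric()))
  pts <- lapply(seq_len(nTracks), function(i) {
    len <- sample(3:nFrames, 1)
    t0 <- sample.int(nFrames - len + 1, 1) - 1L
    x0 <- runif(1, 0, pathLength - 1)
    v <- runif(1, -2, 2)
    pos <- pmin(pmax(x0 + v * (seq_len(len) - 1), 0), pathLength - 1)
    data.frame(id = i, frame = t0 + seq_len(len) - 1L, position = pos)
  })
  do.call(rbind, pts)
}

# --- oracles ---------------------------------------------------------------

oracleRecall <- function(gt, pred, tol = 3.2) {
  out <- numeric(0)
  for (gid in unique(gt$id)) {
    g <- gt[gt$id == gid, ]
    best <- 0
    for (pid in unique(pred$id)) {
      p <- pred[pred$id == pid, ]
      hits <- 0
      for (k in seq_len(nrow(g))) {
        row <- p[p$frame == g$frame[k], ]
        if (nrow(row) && any(sqrt((row$position - g$position[k])^2) <= tol))
          hits <- hits + 1
      }
      best <- max(best, hits / nrow(g))
    }
    out <- c(out, best)
  }
  out
}

oraclePrecision <- function(gt, pred, tol = 3.2) {
  out <- numeric(0)
  for (pid in unique(pred$id)) {
    p <- pred[pred$id == pid, ]
    best <- 0
    for (gid in unique(gt$id)) {
      g <- gt[gt$id == gid, ]
      hits <- 0
      for (k in seq_len(nrow(p))) {
        row <- g[g$frame == p$frame[k], ]
        if (nrow(row) && any(abs(row$position - p$position[k]) <= tol))
          hits <- hits + 1
      }
      best <- max(best, hits / nrow(p))
    }
    out <- c(out, best)
  }
  out
}

oracleGapScore <- function(gaps, gt, pred, tol = 3) {
  if (!nrow(gaps)) return(NA_real_)
  res <- logical(0)
  for (k in seq_len(nrow(gaps))) {
    ok <- TRUE
    for (f in gaps$start[k] + seq_len(gaps$len[k]) - 1L) {
      gp <- gt$position[gt$id == gaps$id[k] & gt$frame == f]
      pp <- pred$position[pred$frame == f]
      if (!length(gp) || !length(pp) || !any(abs(pp - gp[1]) <= tol))
        ok <- FALSE
    }
    res <- c(res, ok)
  }
  mean(res)
}

# raster crossing oracle without any morphology library: explicit pixel
# loops, disc membership by Euclidean distance, prediction dilation by
# Chebyshev distance <= 1
oracleCrossingScore <- function(gt, pred, dims, coverFrac = 0.7,
                                radius = 16) {
  rast <- function(tr) {
    # connected-line rasterisation: consecutive frames joined by
    # interpolated pixels, naive per-pair loop
    tr <- tr[order(tr$frame), ]
    m <- matrix(FALSE, dims[1], dims[2])
    put <- function(r, x) {
      c <- min(max(round(x), 0), dims[2] - 1) + 1L
      if (r + 1 >= 1 && r + 1 <= dims[1]) m[r + 1, c] <<- TRUE
    }
    for (k in seq_len(nrow(tr))) {
      put(tr$frame[k], tr$position[k])
      if (k < nrow(tr) && tr$frame[k + 1] == tr$frame[k] + 1) {
        dx <- tr$position[k + 1] - tr$position[k]
        nst <- max(2, ceiling(abs(dx)) + 1)
        for (s in seq(0, 1, length.out = nst))
          put(round(tr$frame[k] + s), tr$position[k] + s * dx)
      }
    }
    m
  }
  gR <- lapply(split(gt, gt$id), rast)
  if (length(gR) < 2) return(NA_real_)
  pR <- lapply(split(pred, pred$id), function(tr) {
    m <- rast(tr)
    d <- matrix(FALSE, dims[1], dims[2])
    for (r in seq_len(dims[1])) for (c in seq_len(dims[2]))
      if (m[r, c])
        d[max(1, r - 1):min(dims[1], r + 1),
          max(1, c - 1):min(dims[2], c + 1)] <- TRUE
    d
  })
  total <- 0; resolved <- 0
  ids <- seq_along(gR)
  for (a in ids) for (b in ids) {
    if (a >= b) next
    dots <- which(gR[[a]] & gR[[b]], arr.ind = TRUE)
    if (!nrow(dots)) next
    # group dots into crossings: connected if their discs overlap the
    # same dilated region; reproduce the labelling by growing discs
    # (disc membership by Euclidean distance, offsets enumerated once)
    disc <- matrix(FALSE, dims[1], dims[2])
    for (k in seq_len(nrow(dots)))
      for (dr in -radius:radius) for (dc in -radius:radius)
        if (dr * dr + dc * dc <= radius^2) {
          r <- dots[k, 1] + dr; c <- dots[k, 2] + dc
          if (r >= 1 && c >= 1 && r <= dims[1] && c <= dims[2])
            disc[r, c] <- TRUE
        }
    lab <- matrix(0L, dims[1], dims[2])
    nl <- 0L
    for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
      if (!disc[r, c] || lab[r, c]) next
      nl <- nl + 1L
      queue <- list(c(r, c)); lab[r, c] <- nl
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || cc < 1 || rr > dims[1] || cc > dims[2]) next
          if (disc[rr, cc] && !lab[rr, cc]) {
            lab[rr, cc] <- nl
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
    for (l in seq_len(nl)) {
      for (tk in c(a, b)) {
        seg <- which(gR[[tk]] & lab == l)
        if (!length(seg)) next
        total <- total + 1
        hit <- FALSE
        for (pr in pR)
          if (sum(pr[seg]) / length(seg) >= coverFrac) hit <- TRUE
        if (hit) resolved <- resolved + 1
      }
    }
  }
  if (total == 0) return(NA_real_)
  resolved / total
}

# direct hit-miss correlation over all pixels (seed-detection oracle)
oracleSeeds <- function(skel) {
  at <- function(r, c) {
    if (r < 1 || c < 1 || r > nrow(skel) || c > ncol(skel)) 0 else skel[r, c]
  }
  out <- NULL
  for (r in seq_len(nrow(skel))) for (c in seq_len(ncol(skel))) {
    if (!skel[r, c]) next
    if (at(r - 1, c - 1) || at(r - 1, c) || at(r - 1, c + 1)) next
    if (at(r, c - 1) || at(r, c + 1)) next
    out <- rbind(out, c(r - 1L, c - 1L))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# closed-form parameter tally of the shared U-Net (oracle for the
# compiled network's count)
oracleParamCount <- function(base, depth, cin, cout, head) {
  n <- 0
  convblock <- function(ci, co) 9 * ci * co + co + 2 * co  # W + b + BN(g, beta)
  chans <- base * 2^(0:depth)
  for (d in seq_len(depth)) {
    ci <- if (d == 1) cin else chans[d - 1]
    n <- n + convblock(ci, chans[d]) + convblock(chans[d], chans[d])
  }
  n <- n + convblock(chans[depth], chans[depth + 1]) +
    convblock(chans[depth + 1], chans[depth + 1])
  for (d in depth:1) {
    n <- n + convblock(chans[d + 1], chans[d]) +   # up-convolution
      convblock(2 * chans[d], chans[d]) + convblock(chans[d], chans[d])
  }
  if (head == "map") n + base * cout + cout else n + base * 2 + 2
}
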